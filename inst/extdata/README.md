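# External data

This directory ships no survey data. The package's tests and examples
generate everything they need programmatically via `simulate_study()`.

## tiger/

The 2014–2015 Nagarahole tiger camera-trap survey (162 stations, 45 days,
86 identified tigers, 355 detection events) is distributed as a source
archive with the journal article that reported it, under a USGS software
release notice, and is not redistributed here. To run the tiger re-analysis
in `tests/testthat/test-acceptance.R`, convert the deposited data to the
canonical CSV schemas (see `?read_grid`, `?read_traps`, `?parse_survey`,
`?read_schedule`) and place them in this directory as

    tiger/grid.csv        # 500 m x 500 m habitat grid of the 1130 km^2 domain
    tiger/traps.csv       # trap_id, x, y (km), T (days), deploy_start
    tiger/detections.csv  # individual_id, trap_id, time (days, trap clock)
    tiger/schedule.csv    # day/night segments, or build from a sunrise table
                          # with build_day_night_schedule()

The adapter point is `parse_survey()`; no code changes are needed.
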