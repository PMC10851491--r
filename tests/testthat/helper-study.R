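# A small simulated study shared across test files (built once per session).
.studyCache <- new.env(parent = emptyenv())

smallStudy <- function() {
  if (is.null(.studyCache$study)) {
    cfg <- simConfig(seed = 42L, nCases = 800L, years = 2001:2002)
    .studyCache$study <- c(list(config = cfg), simulateStudy(cfg))
  }
  .studyCache$study
}

# Record batch with planted violations of each exclusion rule, one rule per
# record, plus clean records. Uses real block groups from `crosswalk`.
plantedRecords <- function(crosswalk) {
  ok <- crosswalk$geoid12[!is.na(crosswalk$label) &
                            crosswalk$total_population > 0]
  g <- ok[1]
  mk <- function(id, date, geoid = g, age = 55, state = "25",
                 cause = "I21.9") {
    data.frame(record_id = id, death_date = as.Date(date), geoid12 = geoid,
               age = age, sex = "Female", race = "White", education = "HS",
               state = state, cause_code = cause, stringsAsFactors = FALSE)
  }
  rbind(
    mk("ext1", "2002-06-15", cause = "V01.1"),
    mk("ext2", "2002-06-15", cause = "X60"),
    mk("ext3", "2002-06-15", cause = "S02.9"),
    mk("age1", "2002-06-15", age = 17),
    mk("age2", "2002-06-15", age = 2),
    mk("geo1", "2002-06-15", geoid = NA_character_),
    mk("geo2", "2002-06-15", geoid = "25025010101"),   # tract-level, 11 chars
    mk("geo3", "2002-06-15", geoid = "250250101XX1"),
    mk("geo4", "2002-06-15", geoid = "123"),
    mk("st1", "2002-06-15", geoid = "060371234561"),   # CA geoid, MA state
    mk("win1", "2000-12-30"),
    mk("win2", "2017-01-02"),
    mk("pop1", "2002-06-15", geoid = "250259999991"),  # not in crosswalk
    mk("pop2", "2002-06-15", geoid = "250259999992"),
    mk("leap1", "2004-12-31"),
    mk("leap2", "2005-01-02"),
    mk("leap3", "2005-01-04"),
    mk("ok1", "2002-06-15"),
    mk("ok2", "2003-08-02"),
    mk("ok3", "2002-01-20"),
    mk("ok4", "2004-07-07"),
    mk("ok5", "2002-11-11"))
}

plantedCounts <- c(3L, 2L, 4L, 1L, 2L, 2L, 3L)
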