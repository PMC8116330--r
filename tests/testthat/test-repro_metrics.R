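test_that("reporting rounding is one-decimal, half away from zero", {
  expect_identical(round_half_up(26.25), 26.3)
  expect_identical(round_half_up(-26.25), -26.3)
  expect_identical(round_half_up(100 * 9 / 41), 22.0)
  expect_identical(as_pct(12, 1053), 1.1)
  expect_error(as_pct(1, 0), "zero denominator")
})

test_that("event-log validation enforces fate vocabulary and flag rules", {
  ok <- data.frame(female_id = "f", day = 1:2,
                   fate = c("wind", "hatched"))
  expect_silent(egg_events(ok))
  bad_fate <- transform(ok, fate = c("wind", "exploded"))
  expect_error(egg_events(bad_fate), "unknown fate")
  bad_wind <- data.frame(female_id = "f", day = 1, fate = "wind",
                         offspring_id = "x", parthenote = NA)
  expect_error(egg_events(bad_wind), "wind egg cases")
  bad_flag <- data.frame(female_id = "f", day = 1, fate = "infertile",
                         offspring_id = NA, parthenote = TRUE)
  expect_error(egg_events(bad_flag), "developed egg")
  expect_error(egg_events(data.frame(female_id = "f")), "lacks column")
})

test_that("summarize_female reproduces the published per-female examples", {
  ev <- ai_trial_events()
  s034 <- summarize_female(ev[ev$female_id == "034", ])
  expect_identical(s034$n_eggs, 19L)
  expect_identical(s034$n_fertile_ai, 5L)
  expect_identical(s034$fertility_pct, 26.3)
  expect_identical(s034$hatchability_pct, 26.3)
  expect_identical(s034$fertility_duration_days, 44L)

  s854 <- summarize_female(ev[ev$female_id == "854", ])
  expect_identical(s854$n_eggs, 41L)
  expect_identical(s854$n_fertile_ai, 11L)
  expect_identical(s854$n_hatched_ai, 9L)
  expect_identical(s854$n_parthenote, 1L)
  expect_identical(s854$fertility_pct, 26.8)
  expect_identical(s854$hatchability_pct, 22.0)
  expect_identical(s854$fertility_duration_days, 107L)

  s063 <- summarize_female(ev[ev$female_id == "063", ])
  expect_identical(s063$n_eggs, 16L)
  expect_identical(s063$fertility_pct, 0)
  expect_true(is.na(s063$fertility_duration_days))

  expect_error(summarize_female(ev), "mix several females")
})

test_that("whole fixture matches every printed fertility/hatchability figure", {
  counts <- ai_trial_counts()
  sm <- summarize_females(ai_trial_events(counts))
  m <- merge(sm, counts, by = "female_id")
  raw_mode <- m$female_id == "307"  # printed fertility there includes parthenotes
  expect_identical(m$fertility_pct[!raw_mode],
                   m$fertility_pct_printed[!raw_mode])
  expect_identical(m$hatchability_pct, m$hatchability_pct_printed)
  ev <- ai_trial_events(counts)
  s307 <- summarize_female(ev[ev$female_id == "307", ],
                           include_parthenotes = TRUE)
  expect_identical(s307$fertility_pct, 7.7)
  # durations: last-minus-first convention (printed uses 1 for one-day layers)
  multi <- m$n_fertile_ai >= 2L
  expect_identical(m$fertility_duration_days[multi],
                   as.integer(m$duration_printed[multi]))
  expect_true(all(m$fertility_duration_days[m$n_fertile_ai == 1L] == 0L))
})

test_that("fate conservation and pre-insemination exclusion hold", {
  ev <- ai_trial_events()
  sm <- summarize_females(ev)
  for (f in sm$female_id) {
    fe <- ev[ev$female_id == f, ]
    expect_identical(sm$n_laid[sm$female_id == f], nrow(fe))
    expect_identical(nrow(fe), sum(table(fe$fate)))
  }
  # eggs laid before insemination day are dropped
  pre <- data.frame(female_id = "z", day = c(-5L, 3L, 9L),
                    fate = c("hatched", "infertile", "hatched"))
  s <- summarize_female(pre, insemination_day = 0L)
  expect_identical(s$n_laid, 2L)
  expect_identical(s$n_hatched_ai, 1L)
  expect_identical(s$first_fertile_day, 9L)
})

test_that("cohort totals pool counts, not percentages", {
  sm <- summarize_females(ai_trial_events())
  tot <- cohort_totals(sm, ai_trial_groups())
  c24 <- tot[tot$group == "cold24", ]
  expect_identical(c24$n_hatched_ai, 16L)
  expect_identical(c24$pooled_fertility_pct, 28.1)
  # pooled fertility lies within the per-female range
  f24 <- sm[sm$female_id %in% c("793", "626", "583", "370"), ]
  expect_gte(c24$pooled_fertility_pct, min(f24$fertility_pct))
  expect_lte(c24$pooled_fertility_pct, max(f24$fertility_pct))
  # a single-female group equals that female's summary
  one <- cohort_totals(sm[sm$female_id == "854", ], c("854" = "x"))
  expect_identical(one$n_eggs, 41L)
  expect_identical(one$pooled_fertility_pct, 26.8)
  expect_error(cohort_totals(sm, c("854" = "x")), "does not cover")
})

test_that("incidence arithmetic matches the census conventions", {
  inc <- incidence(confirmed = 11, unconfirmed = 1, ungenotyped = 14,
                   total_eggs = 1053, total_fertile = 28)
  expect_identical(inc$observed_pct, 1.1)
  expect_identical(inc$max_pct, 2.5)
  expect_identical(inc$pct_of_fertile, 42.9)
  strict <- incidence(confirmed = 11, unconfirmed = 1, ungenotyped = 14,
                      total_eggs = 1053, include_unconfirmed = FALSE)
  expect_identical(strict$observed_pct, 1.0)
  zero <- incidence(0, 0, 5, total_eggs = 100)
  expect_identical(zero$observed_pct, 0)
  expect_identical(zero$max_pct, 5.0)
  expect_error(incidence(1, total_eggs = 0), "zero total eggs")
  expect_error(incidence(-1, total_eggs = 10), "non-negative")
})

test_that("morphometric means are additive and SEs behave", {
  ms <- morphometrics_summary(sperm_morphometrics())
  get <- function(comp) ms$mean_um[ms$component == comp]
  expect_equal(get("total"), get("head") + get("midpiece") + get("flagellum"))
  expect_equal(get("total"), 178.3)
  # additivity on arbitrary random input too
  set.seed(3)
  rnd <- data.frame(head = rnorm(30, 50), midpiece = rnorm(30, 20),
                    flagellum = rnorm(30, 100))
  mr <- morphometrics_summary(rnd)
  g2 <- function(comp) mr$mean_um[mr$component == comp]
  expect_equal(g2("total"), g2("head") + g2("midpiece") + g2("flagellum"))
  # identical cells: SE exactly zero
  same <- data.frame(head = c(5, 5), midpiece = c(2, 2), flagellum = c(9, 9))
  expect_true(all(morphometrics_summary(same)$se_um == 0))
  expect_error(morphometrics_summary(data.frame(head = 1:3)), "missing component")
  expect_error(morphometrics_summary(transform(same, head = c(5, NA))),
               "missing head")
  expect_error(morphometrics_summary(same[1, ]), "at least two")
})

test_that("recovered means from noisy synthetic cells are within 2 SE", {
  set.seed(13)
  n <- 50
  cells <- data.frame(head = rnorm(n, 57.7, 1.4),
                      midpiece = rnorm(n, 19.9, 1.1),
                      flagellum = rnorm(n, 100.7, 4.2))
  ms <- morphometrics_summary(cells)
  truth <- c(total = 178.3, head = 57.7, midpiece = 19.9, flagellum = 100.7)
  for (comp in names(truth)) {
    row <- ms[ms$component == comp, ]
    expect_lt(abs(row$mean_um - truth[[comp]]), 2 * row$se_um)
  }
})
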