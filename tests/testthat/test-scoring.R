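test_that("event codes classify to the correct category and subtype", {
  cases <- list(
    dic        = c("UNSTABLE_EXCHANGE", "DICENTRIC"),
    r          = c("UNSTABLE_EXCHANGE", "CENTRIC_RING"),
    "t(unbal)" = c("UNSTABLE_EXCHANGE", "UNBALANCED_TRANSLOCATION"),
    "t(bal)"   = c("STABLE_EXCHANGE", "BALANCED_TRANSLOCATION"),
    ace        = c("EXCESS_FRAGMENT", "TERMINAL_FRAGMENT"))
  for (code in names(cases)) {
    ev <- classify_event(code)
    expect_identical(ev$category, cases[[code]][1])
    expect_identical(ev$subtype, cases[[code]][2])
    expect_identical(classify_event(toupper(code))$subtype, ev$subtype)
  }
  expect_error(classify_event("xyz"), "xyz.*accepted codes")
  expect_error(classify_event("dic", chromosomes = "5"), "at least 2")
  expect_error(classify_event("ace", chromosomes = "27"), "1-22")
  cx <- classify_event("cx4")
  expect_identical(cx$breaks, 4L)
})

test_that("minimal break counting: 2 per exchange, 1 per fragment, override for complex", {
  expect_identical(count_breaks("."), 0L)
  expect_identical(count_breaks("t(bal)"), 2L)
  expect_identical(count_breaks("dic;ace"), 3L)
  expect_identical(count_breaks("cx5;ace"), 6L)
  expect_identical(count_breaks(cell_record("c", 1, c("r", "t(unbal)", "ace"))), 5L)
})

test_that("a cell is aberrant iff it carries any aberration", {
  expect_false(is_aberrant(cell_record("c", 0)))
  expect_true(is_aberrant(cell_record("c", 0, "ace")))
})

test_that("tabulation reproduces known compositions and is order-invariant", {
  # 500 control cells: 18 fragment-only + 4 single-exchange aberrations in 22 cells
  codes <- c(rep("ace", 18), rep("t(bal)", 2), rep("dic", 2), rep(".", 478))
  rec <- data.frame(cell_id = sprintf("c%03d", 1:500), dose_gy = 0,
                    event_codes = codes)
  tab <- tabulate_records(rec)
  expect_identical(tab$breaks, 26L)
  expect_identical(tab$aberrant_cells, 22L)
  expect_identical(tab$total_aberrations, 22L)
  expect_equal(tab$breaks_pct, 5.2)
  expect_equal(tab$aberrant_cells_pct, 4.4)

  # empty cells at a dose level: zero counts, zero frequencies
  rec2 <- rbind(rec, data.frame(cell_id = sprintf("d%03d", 1:200),
                                dose_gy = 0.1, event_codes = "."))
  tab2 <- tabulate_records(rec2)
  row01 <- tab2[tab2$dose_gy == 0.1, ]
  expect_identical(row01$total_aberrations, 0L)
  expect_identical(row01$breaks_pct, 0)

  # order invariance
  perm <- rec2[rev(seq_len(nrow(rec2))), ]
  expect_equal(tabulate_records(perm), tab2)

  # a multi-event cell counts once as aberrant, each event toward its category
  rec3 <- data.frame(cell_id = c("a", "b"), dose_gy = 0,
                     event_codes = c("dic;t(bal);ace", "."))
  tab3 <- tabulate_records(rec3)
  expect_identical(tab3$aberrant_cells, 1L)
  expect_identical(tab3$total_aberrations, 3L)
  expect_identical(tab3$breaks, 5L)

  expect_error(tabulate_records(list()), "no records")
})

test_that("scoring-table invariants are enforced", {
  bad <- data.frame(dose_gy = 0, cells_scored = 100, breaks = 5,
                    aberrant_cells = 3, stable_exchanges = 1,
                    unstable_exchanges = 1, excess_fragments = 1,
                    total_aberrations = 5)
  expect_error(as_scoring_table(bad), "total_aberrations")
  bad$excess_fragments <- NULL
  bad$total_aberrations <- 2
  expect_error(as_scoring_table(bad), "aberrant_cells")
})

test_that("simulator bookkeeping round-trips through tabulation", {
  cfg <- sim_config(doses = c(0, 0.5), cells_per_dose = c(80, 80), seed = 11)
  rec <- simulate_scoring(cfg)
  tab <- tabulate_records(rec)
  # recount by splitting the code strings directly
  for (d in cfg$doses) {
    codes <- rec$event_codes[rec$dose_gy == d]
    evs <- unlist(strsplit(codes[codes != "."], ";"))
    row <- tab[tab$dose_gy == d, ]
    expect_identical(row$excess_fragments, sum(evs == "ace"))
    expect_identical(row$stable_exchanges, sum(evs == "t(bal)"))
    expect_identical(row$unstable_exchanges,
                     sum(evs %in% c("dic", "r", "t(unbal)")))
    expect_identical(row$aberrant_cells, sum(codes != "."))
    expect_identical(row$breaks,
                     row$excess_fragments + 2L * (row$stable_exchanges +
                                                  row$unstable_exchanges))
  }
})

test_that("per-cell TSV and per-dose CSV round-trip", {
  rec <- simulate_scoring(sim_config(doses = c(0, 1), cells_per_dose = 40,
                                     seed = 3))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_cell_tsv(rec, p1)
  back <- read_cell_tsv(p1)
  expect_equal(back$event_codes, rec$event_codes)
  expect_equal(tabulate_records(back), tabulate_records(rec))

  tab <- tabulate_records(rec)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_scoring_csv(tab, p2)
  expect_equal(read_scoring_csv(p2), tab)
})
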