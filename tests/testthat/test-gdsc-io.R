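write_csv_tmp <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

test_that("drug list loading deduplicates, drops unmapped, sorts", {
  dl <- write_csv_tmp(data.frame(
    drug_id = c("d3", "d1", "d3", "d2", "d1"),
    name = paste0("n", 1:5)))
  sm <- write_csv_tmp(data.frame(
    drug_id = c("d1", "d2", "d3"),
    canonical_smiles = c("CC", "CO", "CN")))
  drugs <- load_drug_list(dl, sm)
  expect_identical(drugs$drug_id, c("d1", "d2", "d3"))
  expect_identical(drugs$canonical_smiles, c("CC", "CO", "CN"))

  # a drug without a SMILES mapping is dropped with a warning
  sm2 <- write_csv_tmp(data.frame(drug_id = c("d1", "d2"),
                                  canonical_smiles = c("CC", "CO")))
  expect_warning(d2 <- load_drug_list(dl, sm2), "without a SMILES")
  expect_identical(d2$drug_id, c("d1", "d2"))

  # permuted input rows give identical output
  dl_perm <- write_csv_tmp(data.frame(
    drug_id = c("d2", "d3", "d1", "d1", "d3"),
    name = paste0("n", 1:5)))
  expect_identical(load_drug_list(dl_perm, sm)$drug_id, drugs$drug_id)

  bad <- write_csv_tmp(data.frame(id = "x", label = "y"))
  expect_error(load_drug_list(bad, sm), "schema error")

  # a column-rename map adapts raw export headers to the schema
  raw <- write_csv_tmp(data.frame(`Drug ID` = c("d1", "d2"),
                                  `Drug Name` = c("a", "b"),
                                  check.names = FALSE))
  mapped <- load_drug_list(raw, sm2,
                           col_map = c(drug_id = "Drug ID",
                                       name = "Drug Name"))
  expect_identical(mapped$drug_id, c("d1", "d2"))
  expect_error(load_drug_list(raw, sm2, col_map = c(drug_id = "nope")),
               "absent from file")
})

test_that("cell lines with fewer than the required features are removed", {
  df <- data.frame(cell_id = paste0("c", 1:5), tissue = "lung",
                   f1 = c(1, 0, 1, NA, 1), f2 = c(0, 1, NA, NA, 1),
                   f3 = c(1, 1, 1, 1, 0))
  path <- write_csv_tmp(df)
  cells <- load_cell_lines(path)          # default: complete cells only
  expect_identical(cells$cell_id, c("c1", "c2", "c5"))
  expect_identical(dim(cells$features), c(3L, 3L))
  expect_true(all(cells$features %in% c(0, 1)))

  # boundary: a cell with exactly required_features is retained
  cells2 <- suppressWarnings(load_cell_lines(path, required_features = 2L))
  expect_identical(cells2$cell_id, c("c1", "c2", "c3", "c5"))

  expect_error(load_cell_lines(path, feature_catalogue = c("f1", "f2")),
               "unknown feature")
})

test_that("long-format feature tables are pivoted and filtered alike", {
  long <- data.frame(
    cell_id = rep(c("c1", "c2"), each = 3),
    tissue = "blood",
    feature_name = rep(c("f1", "f2", "f3"), 2),
    value = c(1, 0, 1, 1, 1, 0))[-5, ]   # c2 lacks f2
  path <- write_csv_tmp(long)
  cells <- load_cell_lines(path)
  expect_identical(cells$cell_id, "c1")
  expect_identical(unname(cells$features[1, ]), c(1, 0, 1))
})

test_that("normalization is the documented logistic with its inverse", {
  expect_equal(normalize_ic50(0), 0.5)
  # direct evaluation oracle: x = ln(1e-3) gives 1 / (1 + 10^0.3)
  expect_equal(normalize_ic50(log(1e-3)), 1 / (1 + 10^0.3), tolerance = 1e-12)
  # strictly increasing
  xs <- sort(rnorm(100, sd = 5))
  expect_true(all(diff(normalize_ic50(xs)) > 0))
  # bijection: round trip over a wide range of log-IC50 values
  set.seed(2)
  x <- rnorm(1e4, sd = 8)
  expect_lt(max(abs(denormalize_ic50(normalize_ic50(x)) - x)), 1e-9)
  v <- runif(100, 0.01, 0.99)
  expect_lt(max(abs(normalize_ic50(denormalize_ic50(v)) - v)), 1e-12)
  expect_equal(denormalize_ic50(0.5), 0)
  expect_error(normalize_ic50(Inf), "finite")
  expect_error(denormalize_ic50(1), "domain error")
  # alpha is configurable
  expect_equal(normalize_ic50(2, alpha = -0.5), plogis(1))
})

test_that("interaction tables are filtered, masked and validated", {
  drugs <- data.frame(drug_id = c("d1", "d2", "d3"), name = c("a", "b", "c"),
                      canonical_smiles = c("CC", "CO", "CN"),
                      stringsAsFactors = FALSE)
  feats <- matrix(c(1, 0, 0, 1), 2, 2,
                  dimnames = list(c("c1", "c2"), c("f1", "f2")))
  cells <- structure(list(cell_id = c("c1", "c2"), tissue = c("lung", "lung"),
                          features = feats, n_removed = 0L),
                     class = "cell_line_set")
  ic <- data.frame(
    drug_id = c("d1", "d1", "d2", "d3", "d3", "dX"),
    cell_id = c("c1", "c2", "c1", "c1", "c2", "c1"),
    log_ic50 = c(-2, 0, 1, 3, -1, 9),
    below_max_conc = c(1, 0, 1, 0, 1, 1))
  tab <- build_interaction_table(drugs, cells, write_csv_tmp(ic))
  expect_identical(sum(tab$known), 5L)        # row for dropped drug excluded
  expect_identical(sum(tab$known == 0L), 1L)
  expect_true(all(tab$values[tab$known == 1L] > 0 &
                  tab$values[tab$known == 1L] < 1))
  expect_equal(tab$values["d1", "c1"], normalize_ic50(-2))

  s <- interaction_summary(tab)
  expect_identical(s$total_pairs, 6L)
  expect_equal(s$pct_known, 100 * 5 / 6)

  # max_conc restriction ANDs the masks and keeps values untouched
  sub <- max_conc_subset(tab)
  expect_identical(sum(sub$known), 3L)
  expect_identical(sub$values, tab$values)
  all_on <- tab; all_on$below_max_conc <- tab$known
  expect_identical(max_conc_subset(all_on)$known, tab$known)

  dup <- rbind(ic, ic[1, ])
  expect_error(build_interaction_table(drugs, cells, write_csv_tmp(dup)),
               "duplicate pair \\(d1, c1\\)")
})

test_that("below_max_conc defaults to 1 when the column is absent", {
  drugs <- data.frame(drug_id = "d1", name = "a", canonical_smiles = "CC",
                      stringsAsFactors = FALSE)
  feats <- matrix(1, 1, 1, dimnames = list("c1", "f1"))
  cells <- structure(list(cell_id = "c1", tissue = "lung",
                          features = feats, n_removed = 0L),
                     class = "cell_line_set")
  ic <- data.frame(drug_id = "d1", cell_id = "c1", log_ic50 = 0.5)
  tab <- build_interaction_table(drugs, cells, write_csv_tmp(ic))
  expect_identical(tab$below_max_conc[1, 1], 1L)
})

test_that("serialization round-trips and is byte-deterministic", {
  tab <- toy_table(n_drugs = 5L, n_cells = 6L, density = 0.7, seed = 3L)
  d1 <- tempfile(); d2 <- tempfile()
  write_interaction_table(tab, d1)
  write_interaction_table(tab, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  back <- read_interaction_table(d1)
  expect_identical(sum(back$known), sum(tab$known))
  expect_equal(back$values, tab$values)
  expect_identical(back$cells$tissue, tab$cells$tissue)

  # checksum tampering is detected
  writeLines("x,y", file.path(d1, "known.csv"))
  expect_error(read_interaction_table(d1), "checksum")
})
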