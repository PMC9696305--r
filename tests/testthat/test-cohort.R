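test_that("a minimal well-formed CSV reads into a validated cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "pair_id,twin_index,zygosity,age,sex,vol",
    "A,1,MZ,40,F,5.1",
    "A,2,MZ,40,F,5.3",
    "B,1,MZ,55,M,6.0",
    "B,2,MZ,55,M,6.2"), f)
  co <- read_cohort(f)
  expect_s3_class(co, "twin_cohort")
  expect_equal(n_pairs(co), 2L)
  expect_equal(phenotype_names(co), "vol")
})

test_that("reader rejects malformed input with targeted errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "pair_id,twin_index,zygosity,age,sex,vol",
    "A,1,MZ,40,F,5.1",
    "A,2,MZ,40,F,5.3",
    "A,3,MZ,40,F,5.0"), f)
  expect_error(read_cohort(f), "row count other than two")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair_id,twin_index,age,sex,vol",
               "A,1,40,F,5.1", "A,2,40,F,5.3"), f2)
  expect_error(read_cohort(f2), "zygosity")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair_id,twin_index,zygosity,age,sex,vol",
               "A,1,MZ,40,F,abc", "A,2,MZ,40,F,5.3"), f3)
  expect_error(read_cohort(f3), "non-numeric")
})

test_that("schema remapping resolves non-canonical column names", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("famid,ix,zyg,age,sex,vol",
               "A,1,MZ,40,F,5.1", "A,2,MZ,40,F,5.3",
               "B,1,DZ,60,M,6.1", "B,2,DZ,60,M,6.5"), f)
  co <- read_cohort(f, schema = c(pair_id = "famid", twin_index = "ix",
                                  zygosity = "zyg"))
  expect_equal(n_pairs(co, "DZ"), 1L)
})

test_that("validation rejects corrupted cohorts (property over corruptions)", {
  base <- data.frame(
    pair_id = rep(c("A", "B"), each = 2L),
    individual_id = c("A1", "A2", "B1", "B2"),
    twin_index = rep(1:2, 2L), zygosity = rep(c("MZ", "DZ"), each = 2L),
    age = 50, sex = "F", vol = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  corruptions <- list(
    function(d) { d$age[2L] <- -1; d },          # negative age
    function(d) { d$age[1L] <- Inf; d },         # non-finite age
    function(d) { d$sex[4L] <- "M"; d },         # opposite-sex pair
    function(d) { d$zygosity[2L] <- "DZ"; d },   # mixed zygosity in a pair
    function(d) { d$individual_id[2L] <- "A1"; d }, # duplicated member id
    function(d) { d$vol[3L] <- Inf; d },         # non-finite phenotype
    function(d) { d$pair_id[3L] <- "A"; d })     # pair with != 2 rows
  expect_s3_class(twin_cohort(base, "vol"), "twin_cohort")
  for (corrupt in corruptions) {
    expect_error(twin_cohort(corrupt(base), "vol"))
  }
})

test_that("member ordering is deterministic regardless of row order", {
  df <- data.frame(
    pair_id = c("A", "A", "B", "B"),
    individual_id = c("A2", "A1", "B1", "B2"),
    twin_index = c(2L, 1L, 1L, 2L),
    zygosity = "MZ", age = 50, sex = "F",
    vol = c(9, 1, 3, 4), stringsAsFactors = FALSE)
  co1 <- twin_cohort(df, "vol")
  co2 <- twin_cohort(df[c(4, 1, 3, 2), ], "vol")
  expect_identical(as.data.frame(co1), as.data.frame(co2))
  pw <- pair_wide(co1, "vol")
  expect_equal(pw$y1, c(1, 3))  # twin_index 1 first
  expect_equal(pw$y2, c(9, 4))
})

test_that("write/read round trip is the identity on valid cohorts", {
  co <- generate_cohort(sim_config(n_mz = 4, n_dz = 3, seed = 2))
  # inject a missing phenotype value
  df <- as.data.frame(co)
  df$volume[3L] <- NA
  co <- twin_cohort(df, "volume")

  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(n_pairs(back, "MZ"), 4L)
  expect_equal(n_pairs(back, "DZ"), 3L)
  expect_true(is.na(back$volume[3L]))
  for (col in c("age", "volume")) {
    expect_equal(back[[col]], co[[col]], tolerance = 1e-9)
  }
  expect_identical(back$pair_id, co$pair_id)
  expect_identical(back$sex, co$sex)
})

test_that("round trip preserves pair counts on a simulated 62-pair cohort", {
  co <- generate_cohort(sim_config(n_mz = 43, n_dz = 19, seed = 7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(n_pairs(back, "MZ"), 43L)
  expect_equal(n_pairs(back, "DZ"), 19L)
  expect_equal(nrow(back), 124L)
})

test_that("triplet expansion yields the three member pairs, deterministically", {
  trip <- data.frame(
    pair_id = "T1", individual_id = c("a", "b", "c"), twin_index = 1:3,
    zygosity = "MZ", age = 30, sex = "F", vol = c(1, 2, 3),
    stringsAsFactors = FALSE)
  out1 <- expand_triplets(trip)
  out2 <- expand_triplets(trip)
  expect_identical(out1, out2)
  expect_equal(nrow(out1), 6L)
  expect_setequal(unique(out1$pair_id), c("T1-12", "T1-13", "T1-23"))
  # each member appears in exactly two derived pairs
  expect_equal(as.vector(table(out1$individual_id)[c("a", "b", "c")]),
               c(2L, 2L, 2L))
  # pairs are {a,b}, {a,c}, {b,c}
  got <- lapply(split(out1$individual_id, out1$pair_id), sort)
  expect_equal(got[["T1-12"]], c("a", "b"))
  expect_equal(got[["T1-13"]], c("a", "c"))
  expect_equal(got[["T1-23"]], c("b", "c"))
})

test_that("56 pairs plus 2 triplets read as 62 pairs with a warning", {
  co0 <- generate_cohort(sim_config(n_mz = 42, n_dz = 16, seed = 3))
  df <- as.data.frame(co0)
  third <- function(id, zyg) data.frame(
    pair_id = id, individual_id = paste0(id, "_3"), twin_index = 3L,
    zygosity = zyg, age = df$age[df$pair_id == id][1L],
    sex = df$sex[df$pair_id == id][1L], volume = 1.0,
    stringsAsFactors = FALSE)
  df <- rbind(df, third("MZ0001", "MZ"), third("DZ0001", "DZ"))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  expect_warning(co <- read_cohort(f, triplets = TRUE),
                 "non-independent")
  expect_equal(n_pairs(co), 56L + 2L * 3L)  # 56 plain pairs + 2 triplets x 3
  expect_equal(n_pairs(co), 62L)
})
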