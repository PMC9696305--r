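#' Construct a validated twin cohort
#'
#' A twin cohort is a long-format data frame with one row per individual and
#' exactly two rows per pair, carrying the covariates the classical twin
#' design needs (zygosity, age, sex) plus one or more continuous phenotype
#' columns (e.g. structure volumes in cm^3). Rows are ordered
#' deterministically: by `pair_id`, then ascending `twin_index`, ties broken
#' by `individual_id` — the convention every ordering-sensitive statistic
#' (single-entry intra-pair correlation) relies on.
#'
#' @param data data.frame with columns `pair_id`, `individual_id`,
#'   `twin_index`, `zygosity` (`"MZ"`/`"DZ"`), `age` (years, >= 0), `sex`
#'   (`"M"`/`"F"`), and the phenotype columns.
#' @param phenotypes character vector naming the phenotype columns. Defaults
#'   to every column not among the required ones.
#' @param provenance free-text origin tag (source file, simulation digest).
#' @return A `twin_cohort` object (a data.frame subclass) with attributes
#'   `phenotypes` and `provenance`.
#' @export
twin_cohort <- function(data, phenotypes = NULL, provenance = "") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("pair_id", "individual_id", "twin_index", "zygosity",
                "age", "sex")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(phenotypes)) {
    phenotypes <- setdiff(names(data), required)
  }
  if (length(phenotypes) == 0L) {
    stop("cohort must carry at least one phenotype column", call. = FALSE)
  }
  absent <- setdiff(phenotypes, names(data))
  if (length(absent) > 0L) {
    stop("phenotype column(s) not in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  data$pair_id <- as.character(data$pair_id)
  data$individual_id <- as.character(data$individual_id)
  data$twin_index <- as.integer(data$twin_index)
  data$zygosity <- toupper(as.character(data$zygosity))
  data$sex <- toupper(as.character(data$sex))
  for (p in phenotypes) {
    if (!is.numeric(data[[p]])) {
      orig <- data[[p]]
      pv <- suppressWarnings(as.numeric(orig))
      unparsed <- is.na(pv) & !is.na(orig) & !(trimws(as.character(orig)) %in%
                                                 c("", "NA"))
      if (any(unparsed)) {
        stop("non-numeric value in phenotype column '", p, "'", call. = FALSE)
      }
      data[[p]] <- pv
    }
  }
  if (!is.numeric(data$age)) {
    age <- suppressWarnings(as.numeric(data$age))
    if (any(is.na(age) & !is.na(data$age))) {
      stop("non-numeric age value", call. = FALSE)
    }
    data$age <- age
  }

  ord <- order(data$pair_id, data$twin_index, data$individual_id)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  x <- structure(data,
                 phenotypes = phenotypes,
                 provenance = provenance,
                 class = c("twin_cohort", "data.frame"))
  validate_cohort(x)
  x
}

#' Validate a twin cohort's structural invariants
#'
#' Checks: two rows per pair with distinct individual ids, unique pair ids,
#' MZ/DZ zygosity consistent within pair, same-sex pairs, finite non-negative
#' ages, finite-or-missing phenotype values.
#'
#' @param x a `twin_cohort`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "twin_cohort"))
  phen <- attr(x, "phenotypes")

  if (!all(x$zygosity %in% c("MZ", "DZ"))) {
    stop("zygosity must be 'MZ' or 'DZ'", call. = FALSE)
  }
  if (!all(x$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (any(!is.finite(x$age)) || any(x$age < 0)) {
    stop("age must be finite and non-negative", call. = FALSE)
  }
  for (p in phen) {
    v <- x[[p]]
    if (any(!is.na(v) & !is.finite(v))) {
      stop("non-finite value in phenotype '", p, "'", call. = FALSE)
    }
  }

  counts <- table(x$pair_id)
  if (any(counts != 2L)) {
    bad <- names(counts)[counts != 2L]
    stop("pair(s) without exactly two members: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  sp <- split(x, x$pair_id)
  for (pr in sp) {
    if (pr$individual_id[1L] == pr$individual_id[2L]) {
      stop("pair '", pr$pair_id[1L], "' has duplicated individual ids",
           call. = FALSE)
    }
    if (pr$zygosity[1L] != pr$zygosity[2L]) {
      stop("pair '", pr$pair_id[1L], "' mixes zygosity labels", call. = FALSE)
    }
    if (pr$sex[1L] != pr$sex[2L]) {
      stop("pair '", pr$pair_id[1L], "' is opposite-sex; the design admits ",
           "same-sex pairs only", call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a twin cohort from CSV
#'
#' Expects a header row and comma separation with decimal points. Canonical
#' column names (`pair_id`, `twin_index`, `zygosity`, `age`, `sex`, plus
#' phenotypes) can be remapped through `schema`. Triplet input (three rows
#' per id, `twin_index` 1/2/3) is expanded into the three derived pairs when
#' `triplets = TRUE`.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical names to file
#'   column names, e.g. `c(pair_id = "famid")`. Unmapped names are taken
#'   verbatim.
#' @param phenotypes phenotype column names (canonical side); default: all
#'   remaining columns.
#' @param triplets logical; allow ids with three rows and expand them.
#' @return a validated [twin_cohort].
#' @export
read_cohort <- function(path, schema = NULL, phenotypes = NULL,
                        triplets = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")

  canonical <- c("pair_id", "individual_id", "twin_index", "zygosity",
                 "age", "sex")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      fcol <- schema[[canon]]
      if (!fcol %in% names(raw)) {
        stop("schema maps '", canon, "' to absent column '", fcol, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == fcol] <- canon
    }
  }
  needed <- setdiff(canonical, "individual_id")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0L) {
    stop("input lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"individual_id" %in% names(raw)) {
    raw$individual_id <- paste0(raw$pair_id, "_", raw$twin_index)
  }

  counts <- table(raw$pair_id)
  if (triplets) {
    trip_ids <- names(counts)[counts == 3L]
    if (length(trip_ids) > 0L) {
      trip_rows <- raw[raw$pair_id %in% trip_ids, , drop = FALSE]
      raw <- raw[!raw$pair_id %in% trip_ids, , drop = FALSE]
      expanded <- expand_triplets(trip_rows)
      raw <- rbind(raw, expanded)
      warning("expanded ", length(trip_ids), " triplet set(s) into ",
              3L * length(trip_ids), " statistically non-independent pairs",
              call. = FALSE)
    }
  } else if (any(counts != 2L)) {
    bad <- names(counts)[counts != 2L]
    stop("pair id(s) with a row count other than two (set triplets = TRUE ",
         "for triplet input): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }

  twin_cohort(raw, phenotypes = phenotypes, provenance = path)
}

#' Expand triplet rows into the three derived twin pairs
#'
#' A set of triplets is treated as three pairs for analysis — members (1,2),
#' (1,3) and (2,3) — each inheriting the triplet's zygosity. Derived pair ids
#' are deterministic: `<id>-12`, `<id>-13`, `<id>-23`. The three pairs share
#' members and are therefore not statistically independent; that is accepted
#' by convention in this design.
#'
#' @param data data.frame of triplet rows: three rows per `pair_id` with
#'   `twin_index` 1, 2, 3.
#' @return data.frame of pair rows (six per triplet).
#' @export
expand_triplets <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  out <- list()
  for (tid in unique(data$pair_id)) {
    rows <- data[data$pair_id == tid, , drop = FALSE]
    rows <- rows[order(rows$twin_index, rows$individual_id), , drop = FALSE]
    if (nrow(rows) != 3L) {
      stop("triplet '", tid, "' does not have exactly three members",
           call. = FALSE)
    }
    if (anyDuplicated(rows$individual_id)) {
      stop("triplet '", tid, "' has duplicated individual ids", call. = FALSE)
    }
    combos <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    for (cb in combos) {
      pr <- rows[cb, , drop = FALSE]
      pr$pair_id <- paste0(tid, "-", cb[1L], cb[2L])
      pr$twin_index <- c(1L, 2L)
      out[[length(out) + 1L]] <- pr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a twin cohort to CSV
#'
#' Writes numeric columns with 15 significant digits so that a
#' read/write round trip reproduces the cohort to floating-point resolution.
#' Missing phenotype values become empty cells.
#'
#' @param cohort a [twin_cohort].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  df <- as.data.frame(cohort)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && nm != "twin_index") {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "",
                         formatC(df[[nm]], digits = 15, format = "g"))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Phenotype names of a cohort
#' @param cohort a [twin_cohort].
#' @return character vector.
#' @export
phenotype_names <- function(cohort) attr(cohort, "phenotypes")

#' Count pairs, optionally by zygosity
#' @param cohort a [twin_cohort].
#' @param zygosity `"MZ"`, `"DZ"`, or `NULL` for all pairs.
#' @return integer pair count.
#' @export
n_pairs <- function(cohort, zygosity = NULL) {
  df <- as.data.frame(cohort)
  if (!is.null(zygosity)) df <- df[df$zygosity == zygosity, , drop = FALSE]
  length(unique(df$pair_id))
}

#' Pairwise wide view of one phenotype
#'
#' Reshapes the cohort to one row per pair with columns `y1`, `y2` holding
#' the two members' values under the cohort's deterministic member ordering.
#' Pairs with a missing value are dropped when `complete = TRUE`
#' (complete-pair analysis).
#'
#' @param cohort a [twin_cohort].
#' @param phenotype phenotype column name.
#' @param zygosity optional `"MZ"`/`"DZ"` filter.
#' @param complete drop pairs with any missing value for this phenotype.
#' @return data.frame: `pair_id`, `zygosity`, `age`, `sex`, `y1`, `y2`.
#' @export
pair_wide <- function(cohort, phenotype, zygosity = NULL, complete = TRUE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!phenotype %in% phenotype_names(cohort)) {
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  }
  df <- as.data.frame(cohort)
  if (!is.null(zygosity)) df <- df[df$zygosity == zygosity, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(pair_id = character(), zygosity = character(),
                      age = numeric(), sex = character(),
                      y1 = numeric(), y2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  # rows are already ordered pair_id / twin_index / individual_id
  first <- df[seq(1L, nrow(df), by = 2L), , drop = FALSE]
  second <- df[seq(2L, nrow(df), by = 2L), , drop = FALSE]
  stopifnot(all(first$pair_id == second$pair_id))
  out <- data.frame(pair_id = first$pair_id,
                    zygosity = first$zygosity,
                    age = first$age,
                    sex = first$sex,
                    y1 = first[[phenotype]],
                    y2 = second[[phenotype]],
                    stringsAsFactors = FALSE)
  if (complete) out <- out[stats::complete.cases(out[, c("y1", "y2")]), ,
                           drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Twin cohort: ", n_pairs(x, "MZ"), " MZ + ", n_pairs(x, "DZ"),
      " DZ pairs (", nrow(x), " individuals)\n", sep = "")
  cat("Phenotypes: ", paste(phenotype_names(x), collapse = ", "), "\n",
      sep = "")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("Provenance: ", prov, "\n", sep = "")
  invisible(x)
}
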