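#' Quality-filter a set of Fv structures
#'
#' Applies the structure-quality rules used for dataset building, in order;
#' each rejected structure carries its first failing reason:
#' \describe{
#'   \item{chains}{not a VH/VL heterodimer (a chain empty);}
#'   \item{method}{not solved by X-ray crystallography (or method absent);}
#'   \item{resolution}{resolution worse than `max_resolution` Angstroms
#'     (or absent);}
#'   \item{missing_residues}{an internal gap in either chain's
#'     numbering-implied sequence, or a conserved geometry position
#'     (L35-L38/L85-L88, H36-H39/H89-H92) without a C-alpha.}
#' }
#' Schema positions are allowed to be absent (they gap-encode); the
#' missing-residue policy is the package default documented in the methods
#' vignette, since whole-chain completeness cannot be checked without a
#' reference sequence.
#'
#' @param fvs List of [fv_structure] objects.
#' @param max_resolution Resolution cutoff in Angstroms (default 3.0).
#' @return A list with `kept` (list of structures) and `rejected`
#'   (tibble of `id`, `reason`).
#' @export
quality_filter <- function(fvs, max_resolution = 3.0) {
  reasons <- vapply(fvs, function(fv) {
    if (!inherits(fv, "fv_structure")) return("chains")
    if (!any(fv$residues$chain == "L") || !any(fv$residues$chain == "H")) {
      return("chains")
    }
    if (is.na(fv$method) ||
        !grepl("X-?RAY", toupper(fv$method))) {
      return("method")
    }
    if (is.na(fv$resolution) || fv$resolution > max_resolution) {
      return("resolution")
    }
    for (ch in c("L", "H")) {
      nums <- sort(unique(fv$residues$number[fv$residues$chain == ch]))
      if (length(nums) > 0 &&
          !identical(nums, seq(min(nums), max(nums)))) {
        return("missing_residues")
      }
    }
    geom <- tryCatch({
      conserved_ca_sets(fv)
      NA_character_
    }, error = function(e) "missing_residues")
    if (!is.na(geom)) return(geom)
    NA_character_
  }, character(1))
  kept <- fvs[is.na(reasons)]
  rejected <- tibble(
    id = vapply(fvs[!is.na(reasons)],
                function(fv) if (is.list(fv)) fv$id else NA_character_,
                character(1)),
    reason = reasons[!is.na(reasons)]
  )
  list(kept = kept, rejected = rejected)
}

#' Angle records from Fv structures
#'
#' Summarizes each structure as one tabular record: the amino acids at the
#' schema's positions, the CDR loop lengths, the computed packing angle
#' and the resolution. Structures whose angle cannot be computed are
#' excluded with a message.
#'
#' @param fvs List of [fv_structure] objects.
#' @param schema A [feature_schema] or its name.
#' @return A tibble with columns `id`, `residues`, `l1`, `h2`, `h3`,
#'   `angle_deg`, `resolution`.
#' @export
records_from_fvs <- function(fvs, schema = "gbr4") {
  schema <- as_schema(schema)
  rows <- purrr::map(fvs, function(fv) {
    tryCatch({
      rec <- fv_record(fv, schema)
      rec$angle_deg <- packing_angle(fv)$degrees
      rec$resolution <- fv$resolution
      rec
    }, error = function(e) {
      message(sprintf("Excluding %s: %s", fv$id, conditionMessage(e)))
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(0), residues = character(0),
                  l1 = integer(0), h2 = integer(0), h3 = integer(0),
                  angle_deg = numeric(0), resolution = numeric(0))
  }
  out
}

dedup_key <- function(records) {
  paste(records$residues, sprintf("%.2f", round(records$angle_deg, 2)))
}

#' Non-redundantize angle records
#'
#' Removes redundancy while preserving flexible angles: the key is the
#' feature-residue string together with the packing angle rounded to two
#' decimal places (half-even rounding). Among records with identical keys
#' only the first in input order is kept; records with the same residues
#' but different rounded angles all survive, so an antibody crystallized
#' with different packing angles keeps every distinct angle. Idempotent
#' and order-stable.
#'
#' @param records Angle-record tibble (see [records_from_fvs()]); all rows
#'   must be summarized under the same schema.
#' @return The surviving records, in input order.
#' @export
deduplicate <- function(records) {
  records[!duplicated(dedup_key(records)), , drop = FALSE]
}

#' Random train/test split
#'
#' Selects a uniform random `test_fraction` of the records (without
#' replacement) as the test set; the rest are the training set. The test
#' size is `round(n * test_fraction)`. Reproducible for a fixed seed; the
#' seed default echoes the models' random-state default.
#'
#' @param records Angle-record tibble.
#' @param test_fraction Fraction in (0, 1); default 0.1.
#' @param seed Integer seed; default 100.
#' @return A list of class `dataset_split` with `train`, `test` (tibbles)
#'   and `seed`.
#' @export
split_dataset <- function(records, test_fraction = 0.1, seed = 100) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(records)
  if (n < 2) abort("Need at least 2 records to split")
  n_test <- max(1L, round(n * test_fraction))
  idx <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sample.int(n, n_test)
  })
  structure(
    list(train = records[-sort(idx), , drop = FALSE],
         test = records[sort(idx), , drop = FALSE],
         seed = seed),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train: %d, test: %d (seed %d)\n",
              nrow(x$train), nrow(x$test), x$seed))
  invisible(x)
}

# save/restore global RNG state so package functions that take an explicit
# seed do not disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Temporal hold-out of newly deposited structures
#'
#' Given an older and a newer non-redundant record set prepared under the
#' same schema, returns the records of the newer set whose redundancy key
#' (feature residues + rounded angle) does not occur in the older set --
#' i.e. an independent validation set of structures that only became
#' available later.
#'
#' @param old,new Deduplicated angle-record tibbles under one schema.
#' @return The novel records of `new`, in input order.
#' @export
temporal_holdout <- function(old, new) {
  new[!(dedup_key(new) %in% dedup_key(old)), , drop = FALSE]
}

#' Read/write an angle-record dataset as TSV
#'
#' Columns: `id`, `residues`, `l1`, `h2`, `h3`, `angle_deg`, `resolution`;
#' `'-'` inside `residues` marks unoccupied schema positions.
#'
#' @param records Angle-record tibble.
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the tibble.
#' @export
write_dataset <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = "c", residues = "c", l1 = "i", h2 = "i",
                    h3 = "i", angle_deg = "d", resolution = "d"))
}
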