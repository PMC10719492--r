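#' The four-parameter physicochemical residue encoding
#'
#' Each of the 20 standard amino acids is encoded by four physical
#' parameters: the number of side-chain (non-hydrogen) atoms; compactness,
#' i.e. the number of side-chain atoms on the shortest path from the
#' backbone to the most distal side-chain atom; formal charge at
#' physiological pH (+1 Lys/Arg, -1 Asp/Glu, +0.5 His, 0 otherwise); and
#' the Eisenberg consensus hydrophobicity. Side-chain atom counts and
#' compactness are derived from the canonical side-chain heavy-atom
#' topologies (the derivation is documented in the methods vignette). The
#' table ships as `inst/extdata/encoding.tsv` so it is auditable and
#' swappable; no feature is rescaled or standardized.
#'
#' @return A 20-row tibble with columns `aa`, `sidechain_atoms`,
#'   `compactness`, `charge`, `hydrophobicity`.
#' @examples
#' encoding_table()
#' @export
encoding_table <- function() {
  if (is.null(.vhvl_cache$encoding)) {
    path <- system.file("extdata", "encoding.tsv", package = "vhvlpack",
                        mustWork = TRUE)
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = "ciddd")
    stopifnot(nrow(tab) == 20, !anyDuplicated(tab$aa))
    .vhvl_cache$encoding <- tab
    # channel-major lookup matrix: rows aa, cols the four channels
    m <- as.matrix(tab[, c("sidechain_atoms", "compactness",
                           "charge", "hydrophobicity")])
    rownames(m) <- tab$aa
    .vhvl_cache$encoding_matrix <- m
  }
  .vhvl_cache$encoding
}

#' Encode one amino acid (or a gap) as four reals
#'
#' A gap -- a schema position not occupied in the structure, e.g. `H100C`
#' in a short CDR-H3 -- is encoded as the all-zero vector. This convention
#' is fixed and must be identical at training and prediction time.
#'
#' @param aa One-letter amino-acid code, or `"-"`/`NA` for a gap.
#' @return Numeric vector of length 4: `(sidechain_atoms, compactness,
#'   charge, hydrophobicity)`.
#' @examples
#' encode_residue("H")  # charge component is +0.5
#' encode_residue("-")  # gap: all zeros
#' @export
encode_residue <- function(aa) {
  encoding_table()
  if (length(aa) != 1L) abort("encode_residue() encodes one residue")
  if (is.na(aa) || aa == "-") {
    return(c(sidechain_atoms = 0, compactness = 0,
             charge = 0, hydrophobicity = 0))
  }
  m <- .vhvl_cache$encoding_matrix
  if (!aa %in% rownames(m)) {
    abort(paste0("Unknown amino-acid code: '", aa, "'"))
  }
  m[aa, ]
}

#' Feature schemas
#'
#' Four schemas are supported, differing in which interface residue
#' positions are encoded and whether the three most length-variable CDR
#' loop lengths are appended:
#' \describe{
#'   \item{gbr1}{13 interface positions; 52 features.}
#'   \item{gbr2}{13 positions + loop lengths; 55 features.}
#'   \item{gbr3}{37 interface positions; 148 features.}
#'   \item{gbr4}{37 positions + loop lengths; 151 features.}
#' }
#' The 13-position set (L38, L40, L41, L44, L46, L87, H33, H42, H45, H60,
#' H62, H91, H105) is the genetic-algorithm-selected subset of the full
#' 37-position interface set. Each position contributes its four encoded
#' channels; loop lengths, when present, occupy the final three slots in
#' the order CDR-L1, CDR-H2, CDR-H3.
#'
#' @param name One of `"gbr1"`, `"gbr2"`, `"gbr3"`, `"gbr4"`.
#' @return A list of class `feature_schema` with `name`, `positions`
#'   (ordered residue keys), `loop_lengths` (logical) and `length`
#'   (total feature count).
#' @examples
#' feature_schema("gbr4")$length  # 151
#' @export
feature_schema <- function(name = c("gbr4", "gbr3", "gbr2", "gbr1")) {
  name <- match.arg(name)
  pos13 <- c("L38", "L40", "L41", "L44", "L46", "L87",
             "H33", "H42", "H45", "H60", "H62", "H91", "H105")
  pos37 <- c("L32", "L34", "L36", "L38", "L40", "L41", "L43", "L44", "L46",
             "L50", "L86", "L87", "L89", "L91", "L96", "L98",
             "H33", "H35", "H39", "H42", "H45", "H47", "H50", "H60", "H62",
             "H91", "H99", "H100", "H100A", "H100B", "H100C", "H100D",
             "H100E", "H100F", "H100G", "H103", "H105")
  positions <- if (name %in% c("gbr1", "gbr2")) pos13 else pos37
  loops <- name %in% c("gbr2", "gbr4")
  structure(
    list(name = name, positions = positions, loop_lengths = loops,
         length = 4L * length(positions) + if (loops) 3L else 0L),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema %s> %d positions%s, %d features\n",
              x$name, length(x$positions),
              if (x$loop_lengths) " + 3 loop lengths" else "", x$length))
  invisible(x)
}

as_schema <- function(schema) {
  if (inherits(schema, "feature_schema")) schema else feature_schema(schema)
}

# CDR ranges used for the loop-length features (inclusive Chothia numbers)
.cdr_ranges <- list(
  l1 = list(chain = "L", from = 24L, to = 34L),
  h2 = list(chain = "H", from = 50L, to = 58L),
  h3 = list(chain = "H", from = 95L, to = 102L)
)

#' CDR loop lengths
#'
#' Counts the occupied Chothia positions in the three most length-variable
#' CDRs: CDR-L1 (L24-L34), CDR-H2 (H50-H58) and CDR-H3 (H95-H102).
#' Insertion-coded positions inside the numeric range count (H100A counts
#' toward CDR-H3), so the length grows with loop insertions.
#'
#' @param x An [fv_structure], or a numbered-sequence tibble as returned by
#'   [read_numbered_sequence()] (columns `chain`, `number`, `insertion`).
#' @return A named integer vector `c(l1 =, h2 =, h3 =)`.
#' @export
loop_lengths <- function(x) {
  res <- residue_table(x)
  counts <- vapply(.cdr_ranges, function(r) {
    sum(res$chain == r$chain & res$number >= r$from & res$number <= r$to)
  }, integer(1))
  counts
}

# normalize fv_structure / numbered-sequence tibble / file path to a
# residue tibble with chain, number, insertion, aa, key
residue_table <- function(x) {
  if (inherits(x, "fv_structure")) return(x$residues)
  if (is.character(x) && length(x) == 1L) return(read_numbered_sequence(x))
  if (is.data.frame(x)) {
    stopifnot(all(c("chain", "number", "insertion", "aa") %in% names(x)))
    x <- as_tibble(x)
    if (!"key" %in% names(x)) {
      x$key <- make_residue_key(x$chain, x$number, x$insertion)
    }
    return(x)
  }
  abort("Expected an fv_structure, a residue data frame, or a file path")
}

#' Read a numbered-sequence file
#'
#' Plain-text input for prediction without a structure: one residue per
#' line, `<position><whitespace><one-letter aa>`, e.g. `L38 Q` or
#' `H100A Y`. Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A tibble with columns `key`, `chain`, `number`, `insertion`,
#'   `aa`, in residue-key order.
#' @export
read_numbered_sequence <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    abort(paste0("Malformed numbered-sequence line(s): ",
                 paste(lines[bad], collapse = "; ")))
  }
  keys <- parse_residue_key(vapply(parts, `[[`, "", 1L))
  keys$aa <- toupper(vapply(parts, `[[`, "", 2L))
  ord <- residue_key_rank(keys$chain, keys$number, keys$insertion)
  keys[ord, ]
}

#' Summarize one Fv (or sequence) under a feature schema
#'
#' Produces the tabular record used throughout dataset building: the
#' amino acids occupying the schema's positions as a single string (`'-'`
#' for unoccupied positions) plus the three CDR loop lengths.
#'
#' @param x An [fv_structure], numbered-sequence tibble, or file path.
#' @param schema A [feature_schema] or its name.
#' @param id Identifier; defaults to the structure's id or `"seq"`.
#' @return One-row tibble with columns `id`, `residues`, `l1`, `h2`, `h3`.
#' @export
fv_record <- function(x, schema = "gbr4", id = NULL) {
  schema <- as_schema(schema)
  res <- residue_table(x)
  id <- id %||% if (inherits(x, "fv_structure")) x$id else "seq"
  aa <- res$aa[match(schema$positions, res$key)]
  aa[is.na(aa)] <- "-"
  ll <- loop_lengths(res)
  tibble(id = id, residues = paste(aa, collapse = ""),
         l1 = ll[["l1"]], h2 = ll[["h2"]], h3 = ll[["h3"]])
}

#' Encode one Fv or numbered sequence as a feature vector
#'
#' Concatenates [encode_residue()] over the schema's positions in schema
#' order, then appends the CDR-L1/H2/H3 loop lengths when the schema
#' includes them. Featurization is a pure function: identical inputs give
#' identical vectors.
#'
#' @inheritParams fv_record
#' @return Named numeric vector of length `schema$length`.
#' @examples
#' \dontrun{
#' featurize(read_fv("1abc.pdb"), "gbr1")  # length 52
#' }
#' @export
featurize <- function(x, schema = "gbr4", id = NULL) {
  schema <- as_schema(schema)
  rec <- fv_record(x, schema, id = id)
  drop(features_from_records(rec, schema))
}

#' Feature matrix from summarized records
#'
#' Vectorized featurization of a record table (as produced by [fv_record()]
#' or [records_from_fvs()]): each `residues` string is expanded into the
#' four encoded channels per position, and loop-length columns are appended
#' for schemas that use them.
#'
#' @param records Tibble with a `residues` column (and `l1`, `h2`, `h3`
#'   when the schema includes loop lengths).
#' @param schema A [feature_schema] or its name.
#' @return Numeric matrix, one row per record, `schema$length` columns.
#' @export
features_from_records <- function(records, schema = "gbr4") {
  schema <- as_schema(schema)
  encoding_table()
  m <- .vhvl_cache$encoding_matrix
  np <- length(schema$positions)
  chars <- t(vapply(strsplit(records$residues, ""), function(ch) {
    if (length(ch) != np) {
      abort(sprintf("residues string has %d characters; schema %s needs %d",
                    length(ch), schema$name, np))
    }
    ch
  }, character(np)))
  if (np == 1L) chars <- t(chars)
  enc <- matrix(0, nrow(records), 4L * np)
  known <- rownames(m)
  for (j in seq_len(np)) {
    aa <- chars[, j]
    bad <- !(aa %in% c(known, "-"))
    if (any(bad)) {
      abort(paste0("Unknown amino-acid code: '",
                   paste(unique(aa[bad]), collapse = "', '"), "'"))
    }
    hit <- match(aa, known)
    vals <- m[ifelse(is.na(hit), 1L, hit), , drop = FALSE]
    vals[is.na(hit), ] <- 0
    enc[, (4L * j - 3L):(4L * j)] <- vals
  }
  colnames(enc) <- as.vector(vapply(
    schema$positions,
    function(p) paste0(p, ".", c("atoms", "compact", "charge", "hydro")),
    character(4)))
  if (schema$loop_lengths) {
    stopifnot(all(c("l1", "h2", "h3") %in% names(records)))
    enc <- cbind(enc, l1 = records$l1, h2 = records$h2, h3 = records$h3)
  }
  enc
}
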