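#' Fv structures
#'
#' An `fv_structure` holds one antibody Fv: the Chothia-numbered residues of
#' a paired light and heavy chain, each with its amino-acid identity and
#' (optionally) a C-alpha coordinate, plus the experimental method and
#' resolution when the source file records them.
#'
#' @param id Identifier string (AbDb/PDB style).
#' @param residues Tibble with columns `chain` (`"L"`/`"H"`), `number`,
#'   `insertion` (`""` for none), `aa` (one-letter code) and `x`, `y`, `z`
#'   C-alpha coordinates in Angstroms (`NA` when absent).
#' @param resolution Resolution in Angstroms, or `NA`.
#' @param method Experimental method string (e.g. `"X-RAY DIFFRACTION"`),
#'   or `NA`.
#' @return An object of class `fv_structure`.
#' @export
fv_structure <- function(id, residues, resolution = NA_real_,
                         method = NA_character_) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "number", "insertion", "aa") %in% names(residues)))
  residues <- as_tibble(residues)
  if (!all(c("x", "y", "z") %in% names(residues))) {
    residues$x <- residues$y <- residues$z <- NA_real_
  }
  residues$key <- make_residue_key(residues$chain, residues$number,
                                   residues$insertion)
  dup <- duplicated(residues$key)
  if (any(dup)) {
    abort(paste0("Duplicate residue key(s): ",
                 paste(unique(residues$key[dup]), collapse = ", ")))
  }
  ord <- residue_key_rank(residues$chain, residues$number, residues$insertion)
  residues <- residues[ord, c("key", "chain", "number", "insertion",
                              "aa", "x", "y", "z")]
  structure(
    list(id = id, residues = residues,
         resolution = resolution, method = method),
    class = "fv_structure"
  )
}

#' @export
print.fv_structure <- function(x, ...) {
  n_l <- sum(x$residues$chain == "L")
  n_h <- sum(x$residues$chain == "H")
  cat(sprintf("<fv_structure %s>  L: %d residues, H: %d residues\n",
              x$id, n_l, n_h))
  if (!is.na(x$method)) cat("  method:    ", x$method, "\n")
  if (!is.na(x$resolution)) cat("  resolution:", x$resolution, "A\n")
  invisible(x)
}

# parent-residue map for common modified residues; anything else that is
# not one of the 20 standard codes is dropped with a warning
.nonstandard_map <- c(
  MSE = "M", HYP = "P", SEC = "C", PCA = "E", CSO = "C",
  SEP = "S", TPO = "T", PTR = "Y", MLY = "K", KCX = "K"
)

#' Read a Chothia-numbered antibody PDB file
#'
#' Reads an AbDb-style PDB file containing exactly one Fv (one light and one
#' heavy chain, labelled `L` and `H` by AbDb convention) into an
#' [fv_structure]. Only C-alpha positions are retained; altloc `'A'` is kept
#' when alternate conformers are present. Residue numbers and insertion
#' codes are taken verbatim from the file; no renumbering is attempted.
#' Common modified residues (MSE etc.) are mapped to their parent amino
#' acid; unmappable residues are dropped with a warning. Resolution and
#' experimental method are read from `REMARK 2` / `EXPDTA` header records
#' when present (header-less fixture files are accepted).
#'
#' @param path Path to the PDB file.
#' @param light_chain,heavy_chain Chain identifiers to treat as the light
#'   and heavy chain (defaults follow the AbDb `L`/`H` convention).
#' @param id Identifier for the structure; defaults to the file name
#'   without extension.
#' @return An [fv_structure].
#' @export
read_fv <- function(path, light_chain = "L", heavy_chain = "H", id = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  id <- id %||% sub("\\.[^.]*$", "", basename(path))

  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom

  chains_found <- sort(unique(at$chain))
  wanted <- c(light_chain, heavy_chain)
  if (!all(wanted %in% chains_found)) {
    abort(sprintf(
      "No recognizable light/heavy pair: wanted chains [%s], file has [%s]",
      paste(wanted, collapse = ", "), paste(chains_found, collapse = ", ")))
  }
  extra <- setdiff(chains_found, wanted)
  if (length(extra) > 0) {
    abort(sprintf(
      "More than two chains in %s: found [%s] besides light='%s', heavy='%s'",
      path, paste(extra, collapse = ", "), light_chain, heavy_chain))
  }

  ca <- at[at$elety == "CA" &
             (is.na(at$alt) | at$alt %in% c("", "A")) &
             at$chain %in% wanted, , drop = FALSE]

  resid <- ca$resid
  mapped <- ifelse(resid %in% names(.nonstandard_map),
                   .nonstandard_map[resid],
                   suppressWarnings(bio3d::aa321(resid)))
  ok <- mapped %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (any(!ok)) {
    warn(paste0("Dropping residues with no standard parent amino acid: ",
                paste(unique(resid[!ok]), collapse = ", ")))
    ca <- ca[ok, , drop = FALSE]
    mapped <- mapped[ok]
  }

  residues <- tibble(
    chain = ifelse(ca$chain == light_chain, "L", "H"),
    number = as.integer(ca$resno),
    insertion = ifelse(is.na(ca$insert), "", toupper(ca$insert)),
    aa = unname(mapped),
    x = ca$x, y = ca$y, z = ca$z
  )
  # a residue observed twice (e.g. two altloc-A records) keeps its first CA
  keys <- make_residue_key(residues$chain, residues$number, residues$insertion)
  residues <- residues[!duplicated(keys), , drop = FALSE]
  if (!any(residues$chain == "L") || !any(residues$chain == "H")) {
    abort(paste0("Not a VH/VL heterodimer: ", path))
  }

  hdr <- readLines(path, n = 100L, warn = FALSE)
  res_line <- grep("^REMARK   2 RESOLUTION", hdr, value = TRUE)
  resolution <- NA_real_
  if (length(res_line) > 0) {
    tail_txt <- substring(res_line[1], 23)
    num <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
    if (length(num) > 0) resolution <- as.numeric(num)
  }
  meth_line <- grep("^EXPDTA", hdr, value = TRUE)
  method <- if (length(meth_line) > 0) {
    trimws(substring(meth_line[1], 11))
  } else NA_character_

  fv_structure(id, residues, resolution = resolution, method = method)
}

#' Write an Fv structure as a PDB file
#'
#' Emits one C-alpha ATOM record per residue (residues without coordinates
#' are skipped), preceded by `EXPDTA` and `REMARK 2` header lines when the
#' structure carries a method/resolution. Reading the file back with
#' [read_fv()] recovers the residue keys, amino acids and coordinates.
#'
#' @param fv An [fv_structure].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fv <- function(fv, path) {
  stopifnot(inherits(fv, "fv_structure"))
  res <- fv$residues[!is.na(fv$residues$x), , drop = FALSE]
  hdr <- character(0)
  if (!is.na(fv$method)) {
    hdr <- c(hdr, sprintf("EXPDTA    %s", fv$method))
  }
  if (!is.na(fv$resolution)) {
    hdr <- c(hdr, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                          fv$resolution))
  }
  writeLines(hdr, path)
  chain_id <- ifelse(res$chain == "L", "L", "H")
  bio3d::write.pdb(
    pdb = NULL, file = path, append = length(hdr) > 0,
    xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
    resno = res$number,
    resid = bio3d::aa123(res$aa),
    chain = chain_id,
    insert = ifelse(res$insertion == "", NA, res$insertion),
    elety = rep("CA", nrow(res)),
    o = rep(1, nrow(res)), b = rep(20, nrow(res))
  )
  invisible(path)
}

#' Look up one residue by key
#'
#' Absence is a normal value, not an error: short CDRs legitimately lack
#' inserted positions such as `H100C`.
#'
#' @param fv An [fv_structure].
#' @param key Residue key string, e.g. `"L35"` or `"H100A"`.
#' @return A one-row tibble, or a zero-row tibble when the position is not
#'   occupied.
#' @export
get_residue <- function(fv, key) {
  stopifnot(inherits(fv, "fv_structure"), length(key) == 1L)
  fv$residues[fv$residues$key == key, , drop = FALSE]
}

#' Residues of one Fv as a tibble
#'
#' @param fv An [fv_structure].
#' @return The residue tibble (one row per numbered position, in key order).
#' @export
fv_residues <- function(fv) {
  stopifnot(inherits(fv, "fv_structure"))
  fv$residues
}
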