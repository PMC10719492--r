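#' Parse Chothia residue keys
#'
#' A residue key names one position in a Chothia-numbered Fv: the chain kind
#' (`L` for light, `H` for heavy), the residue number, and an optional
#' single-letter insertion code, written e.g. `"L38"` or `"H100A"`.
#'
#' @param keys Character vector of keys such as `"L38"`, `"H100A"`.
#' @return A tibble with columns `key`, `chain`, `number`, `insertion`
#'   (empty string when there is no insertion code).
#' @examples
#' parse_residue_key(c("L38", "H100A"))
#' @export
parse_residue_key <- function(keys) {
  m <- regmatches(keys, regexec("^([LH])([0-9]+)([A-Za-z]?)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    abort(paste0("Malformed residue key(s): ",
                 paste(keys[bad], collapse = ", ")))
  }
  tibble(
    key = keys,
    chain = vapply(m, `[[`, "", 2L),
    number = as.integer(vapply(m, `[[`, "", 3L)),
    insertion = toupper(vapply(m, `[[`, "", 4L))
  )
}

#' Build residue keys from components
#'
#' @param chain `"L"` or `"H"` (recycled).
#' @param number Integer residue number (Chothia).
#' @param insertion Insertion code, `""` for none.
#' @return Character vector of keys.
#' @export
make_residue_key <- function(chain, number, insertion = "") {
  paste0(chain, number, insertion)
}

# Order residues by (chain L<H, number, insertion) with "" before "A".
residue_key_rank <- function(chain, number, insertion) {
  order(match(chain, c("L", "H")), number,
        match(insertion, c("", LETTERS)))
}
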