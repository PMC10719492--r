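#' Generate a synthetic Fv structure with a prescribed packing angle
#'
#' Builds a Chothia-numbered Fv fixture by inverse construction of the
#' packing-angle definition: the sixteen conserved C-alpha positions are
#' placed exactly on two straight segments whose fitted principal axes
#' form the requested torsion about the centroid-to-centroid axis, so with
#' `jitter_sd = 0` the computed [packing_angle()] equals
#' `target_angle_deg` to numerical precision. The remaining framework and
#' CDR positions are filled with plausibly spaced C-alpha placements and a
#' fixed consensus of residue identities (full framework L1-L107 /
#' H1-H113, with configurable CDR insertions so loop-length features can
#' vary). Gaussian jitter, when requested, is added to every C-alpha
#' after the exact construction. The fixture carries `EXPDTA` /
#' `REMARK 2`-style metadata so quality filtering is exercisable
#' end-to-end. The geometry is schematic, not a physically realistic
#' antibody.
#'
#' @param target_angle_deg Desired packing angle in degrees (default -46,
#'   the natural-antibody mean).
#' @param inter_domain_distance Distance between the two domain centroids
#'   in Angstroms (default 16).
#' @param jitter_sd Isotropic Gaussian noise added to all C-alpha
#'   coordinates, Angstroms (default 0).
#' @param seed Integer seed (used for the jitter).
#' @param id Structure identifier.
#' @param resolution,method Header metadata for the fixture.
#' @param cdr_l1_length,cdr_h2_length,cdr_h3_length Loop lengths; values
#'   above the base lengths (11, 9, 8) add insertion-coded positions
#'   (L30A..., H52A..., H100A...).
#' @param mutations Named character vector of residue overrides, e.g.
#'   `c(L38 = "Q")`.
#' @param path Optional: also write the structure as a PDB file here.
#' @return An [fv_structure].
#' @examples
#' fv <- make_fv_fixture(target_angle_deg = -46)
#' packing_angle(fv)
#' @export
make_fv_fixture <- function(target_angle_deg = -46,
                            inter_domain_distance = 16,
                            jitter_sd = 0, seed = 1,
                            id = sprintf("synth_%+.0f", target_angle_deg),
                            resolution = 1.8,
                            method = "X-RAY DIFFRACTION",
                            cdr_l1_length = 11, cdr_h2_length = 9,
                            cdr_h3_length = 8,
                            mutations = NULL, path = NULL) {
  stopifnot(inter_domain_distance > 0, jitter_sd >= 0,
            cdr_l1_length >= 11, cdr_h2_length >= 9, cdr_h3_length >= 8)

  chain_positions <- function(chain, n_max, inserts) {
    pos <- tibble(chain = chain, number = seq_len(n_max), insertion = "")
    dplyr::bind_rows(pos, inserts)
  }
  ins <- function(chain, number, k) {
    if (k <= 0) return(NULL)
    tibble(chain = chain, number = number, insertion = LETTERS[seq_len(k)])
  }
  res <- dplyr::bind_rows(
    chain_positions("L", 107L, ins("L", 30L, cdr_l1_length - 11L)),
    chain_positions("H", 113L, ins("H", 52L, cdr_h2_length - 9L)),
    ins("H", 100L, cdr_h3_length - 8L)
  )
  res$key <- make_residue_key(res$chain, res$number, res$insertion)
  ord <- residue_key_rank(res$chain, res$number, res$insertion)
  res <- res[ord, ]

  consensus <- strsplit("QVKLSEDRGTAYFWNIHPCM", "")[[1]]
  res$aa <- consensus[(seq_len(nrow(res)) - 1L) %% 20L + 1L]
  if (!is.null(mutations)) {
    hit <- match(names(mutations), res$key)
    if (anyNA(hit)) {
      abort(paste0("Mutation at position(s) not in fixture: ",
                   paste(names(mutations)[is.na(hit)], collapse = ", ")))
    }
    res$aa[hit] <- unname(mutations)
  }

  # background placement: spaced points winding around each chain's axis
  theta <- target_angle_deg * pi / 180
  d_light <- c(1, 0, 0)
  d_heavy <- c(cos(theta), sin(theta), 0)
  o_light <- c(0, 0, 0)
  o_heavy <- c(0, 0, inter_domain_distance)
  axis_of <- function(chain) if (chain == "L") d_light else d_heavy
  origin_of <- function(chain) if (chain == "L") o_light else o_heavy
  idx_in_chain <- stats::ave(seq_len(nrow(res)), res$chain,
                             FUN = seq_along)
  coords <- t(vapply(seq_len(nrow(res)), function(i) {
    ax <- axis_of(res$chain[i]); og <- origin_of(res$chain[i])
    k <- idx_in_chain[i]
    og + ax * ((k - 55) * 0.8) +
      6 * c(0, cos(k * 0.7), sin(k * 0.7)) * if (res$chain[i] == "L") 1 else -1
  }, numeric(3)))

  # exact placement of the sixteen conserved positions on the two lines;
  # the first four sit at negative offsets so the oriented fit points
  # from the L35-L38 (H36-H39) centroid toward the L85-L88 (H89-H92) one
  t_off <- c(-13.3, -9.5, -5.7, -1.9, 1.9, 5.7, 9.5, 13.3)
  li <- match(GEOMETRY_POSITIONS_LIGHT, res$key)
  hi <- match(GEOMETRY_POSITIONS_HEAVY, res$key)
  coords[li, ] <- t(vapply(t_off, function(t) o_light + t * d_light,
                           numeric(3)))
  coords[hi, ] <- t(vapply(t_off, function(t) o_heavy + t * d_heavy,
                           numeric(3)))

  if (jitter_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    coords <- coords + matrix(rnorm(length(coords), sd = jitter_sd),
                              nrow(coords), 3)
  }
  res$x <- coords[, 1]; res$y <- coords[, 2]; res$z <- coords[, 3]

  fv <- fv_structure(id, res[, c("chain", "number", "insertion", "aa",
                                 "x", "y", "z")],
                     resolution = resolution, method = method)
  if (!is.null(path)) write_fv(fv, path)
  fv
}

# position set carrying the planted signal by default: members of both
# the 13- and 37-position schemas, so every schema can learn it
.default_signal_positions <- c("L38", "L44", "L87", "H33", "H45", "H91")

# class-specific residue alphabets used when a class mix is requested:
# hydrophilic / small-neutral / hydrophobic, disjoint and therefore
# separable signatures
.class_alphabets <- list(
  min_outlier = c("R", "K", "D", "E", "N", "Q"),
  normal = c("A", "G", "S", "T", "P", "C"),
  max_outlier = c("I", "L", "V", "F", "M", "W")
)

#' Generate a planted-signal sequence-to-angle dataset
#'
#' Emulates the tabular data the predictor is trained on, with a known
#' ground truth. Residues at `signal_positions` are drawn at random and
#' the angle is a planted function of their encoded hydrophobicity (the
#' channel with the largest dynamic range) plus Gaussian noise:
#' `angle = angle_center + sum(w_p * (hydro(aa_p) - mean_hydro)) + N(0,
#' noise_sd)`. Non-signal positions are uniform draws, inserted CDR-H3
#' positions are occupied at random so loop lengths vary, and everything
#' is a pure function of `seed`.
#'
#' With `class_mix` given (proportions of `min_outlier` / `normal` /
#' `max_outlier`), each record is assigned a class; its signal positions
#' are drawn from a class-specific residue alphabet (hydrophilic, small
#' neutral, hydrophobic -- disjoint, hence separable signatures) and its
#' angle is centred in the class's angle band (-53.5, -45, -36.5 degrees)
#' with a reduced within-class signal, so the class structure is
#' recoverable from sequence and the realized class fractions match the
#' mix up to sampling noise. Angles centre near -46 degrees with ~94%
#' inside \[-50, -40\] under the default mix used for classifier tests.
#'
#' @param n Number of records.
#' @param schema A [feature_schema] or its name.
#' @param signal_positions Schema positions carrying the signal (default:
#'   six positions shared by the 13- and 37-position sets).
#' @param weights Per-position signal weight on the centred
#'   hydrophobicity channel; scalar or vector (default 2).
#' @param noise_sd Gaussian noise on the angle, degrees (default 1).
#' @param angle_center Centre of the angle distribution (default -46).
#' @param class_mix Optional length-3 proportions over
#'   (`min_outlier`, `normal`, `max_outlier`); must sum to 1.
#' @param seed Integer seed.
#' @param path Optional: also write the records as a dataset TSV.
#' @return An angle-record tibble (`id`, `residues`, `l1`, `h2`, `h3`,
#'   `angle_deg`, `resolution`) with attributes `signal_sd` (SD of the
#'   planted signal term) and `achieved` (realized mean/SD of the angle).
#' @export
make_planted_dataset <- function(n, schema = "gbr4",
                                 signal_positions = NULL,
                                 weights = 2, noise_sd = 1,
                                 angle_center = -46, class_mix = NULL,
                                 seed = 1, path = NULL) {
  schema <- as_schema(schema)
  signal_positions <- signal_positions %||% .default_signal_positions
  if (!all(signal_positions %in% schema$positions)) {
    abort("signal_positions must be a subset of the schema's positions")
  }
  weights <- rep_len(weights, length(signal_positions))
  if (!is.null(class_mix)) {
    if (length(class_mix) != 3 || any(class_mix < 0) ||
        abs(sum(class_mix) - 1) > 1e-8) {
      abort(paste0("class_mix must be 3 non-negative proportions summing",
                   " to 1 over (min_outlier, normal, max_outlier)"))
    }
  }

  enc <- encoding_table()
  hydro <- setNames(enc$hydrophobicity, enc$aa)
  aas <- enc$aa

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  np <- length(schema$positions)
  sig_idx <- match(signal_positions, schema$positions)
  # which schema positions are CDR-H3 insertions (occupied at random)
  h3_ins <- grepl("^H100[A-G]$", schema$positions)
  if (any(h3_ins[sig_idx])) {
    abort("signal_positions may not be CDR-H3 insertion positions")
  }

  chars <- matrix(sample(aas, n * np, replace = TRUE), n, np)
  if (any(h3_ins)) {
    # occupy a random-length prefix of H100A.. so CDR-H3 length varies
    n_ins <- sum(h3_ins)
    ext <- sample(0:n_ins, n, replace = TRUE)
    ins_cols <- which(h3_ins)
    for (j in seq_len(n_ins)) {
      chars[ext < j, ins_cols[j]] <- "-"
    }
  } else {
    ext <- sample(0:7, n, replace = TRUE)
  }

  if (is.null(class_mix)) {
    cls <- NULL
    for (k in seq_along(sig_idx)) {
      chars[, sig_idx[k]] <- sample(aas, n, replace = TRUE)
    }
    centred <- function(aa) hydro[aa] - mean(hydro)
    signal <- rowSums(vapply(seq_along(sig_idx), function(k) {
      weights[k] * centred(chars[, sig_idx[k]])
    }, numeric(n)))
    angle <- angle_center + signal + rnorm(n, sd = noise_sd)
  } else {
    cls <- sample(angle_class_levels(), n, replace = TRUE,
                  prob = class_mix)
    centers <- c(min_outlier = -53.5, normal = -45, max_outlier = -36.5)
    signal <- numeric(n)
    for (lv in angle_class_levels()) {
      rows <- which(cls == lv)
      if (length(rows) == 0) next
      alph <- .class_alphabets[[lv]]
      sub <- matrix(sample(alph, length(rows) * length(sig_idx),
                           replace = TRUE),
                    length(rows), length(sig_idx))
      chars[rows, sig_idx] <- sub
      centred <- hydro[as.vector(sub)] - mean(hydro[alph])
      signal[rows] <- rowSums(matrix(0.3 * centred,
                                     length(rows), length(sig_idx)))
    }
    angle <- centers[cls] + signal + rnorm(n, sd = noise_sd)
  }

  out <- tibble(
    id = sprintf("planted_%05d", seq_len(n)),
    residues = apply(chars, 1, paste, collapse = ""),
    l1 = 11L, h2 = 9L, h3 = 8L + as.integer(ext),
    angle_deg = unname(angle),
    resolution = 1.8
  )
  attr(out, "signal_sd") <- sd(signal)
  attr(out, "achieved") <- c(mean = mean(angle), sd = sd(angle))
  if (!is.null(cls)) attr(out, "angle_class") <- cls
  if (!is.null(path)) write_dataset(out, path)
  out
}

#' Generate near-duplicate angle records
#'
#' Produces `k` copies of one record whose angles differ from the base by
#' the given jitters, for exercising the residue-plus-rounded-angle
#' redundancy rule: the survivor count under [deduplicate()] is computable
#' by hand-rounding the jittered angles to two decimals.
#'
#' @param base One-row angle-record tibble.
#' @param k Number of copies.
#' @param angle_jitters Numeric vector of length `k`, degrees.
#' @return A `k`-row angle-record tibble with suffixed ids.
#' @export
make_duplicate_pack <- function(base, k, angle_jitters) {
  stopifnot(is.data.frame(base), nrow(base) == 1,
            length(angle_jitters) == k)
  if (k == 0) return(base[0, , drop = FALSE])
  out <- base[rep(1L, k), , drop = FALSE]
  out$id <- paste0(base$id, "_", seq_len(k))
  out$angle_deg <- base$angle_deg + angle_jitters
  out
}
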