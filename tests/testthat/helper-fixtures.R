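# shared helpers: tiny in-code fixtures used across the suite

# minimal residue tibble for hand-built structures
res_row <- function(chain, number, aa = "A", insertion = "",
                    x = NA_real_, y = NA_real_, z = NA_real_) {
  tibble::tibble(chain = chain, number = number, insertion = insertion,
                 aa = aa, x = x, y = y, z = z)
}

# one-row angle record for dataset tests
record_row <- function(id = "r1", residues = strrep("A", 13),
                       angle_deg = -46, l1 = 11L, h2 = 9L, h3 = 8L,
                       resolution = 1.8) {
  tibble::tibble(id = id, residues = residues, l1 = l1, h2 = h2, h3 = h3,
                 angle_deg = angle_deg, resolution = resolution)
}

# random rigid motion (proper rotation + translation)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = rnorm(3, sd = 50))
}

apply_rigid <- function(fv, motion, reflect = FALSE) {
  xyz <- as.matrix(fv$residues[, c("x", "y", "z")])
  if (reflect) xyz[, 3] <- -xyz[, 3]
  xyz <- xyz %*% t(motion$rot)
  xyz <- sweep(xyz, 2, motion$shift, "+")
  fv$residues$x <- xyz[, 1]
  fv$residues$y <- xyz[, 2]
  fv$residues$z <- xyz[, 3]
  fv
}

# drop one residue (by key) from a structure
drop_residue <- function(fv, key) {
  fv$residues <- fv$residues[fv$residues$key != key, , drop = FALSE]
  fv
}
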