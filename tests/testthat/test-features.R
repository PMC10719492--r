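# independent recomputation of the two topology-derived encoding channels:
# BFS over the canonical side-chain heavy-atom graphs
sidechain_graphs <- list(
  A = list(CB = character(0)),
  R = list(CB = "CG", CG = "CD", CD = "NE", NE = "CZ", CZ = c("NH1", "NH2")),
  N = list(CB = "CG", CG = c("OD1", "ND2")),
  D = list(CB = "CG", CG = c("OD1", "OD2")),
  C = list(CB = "SG"),
  Q = list(CB = "CG", CG = "CD", CD = c("OE1", "NE2")),
  E = list(CB = "CG", CG = "CD", CD = c("OE1", "OE2")),
  G = list(),
  H = list(CB = "CG", CG = c("ND1", "CD2"), ND1 = "CE1", CD2 = "NE2",
           CE1 = "NE2"),
  I = list(CB = c("CG1", "CG2"), CG1 = "CD1"),
  L = list(CB = "CG", CG = c("CD1", "CD2")),
  K = list(CB = "CG", CG = "CD", CD = "CE", CE = "NZ"),
  M = list(CB = "CG", CG = "SD", SD = "CE"),
  F = list(CB = "CG", CG = c("CD1", "CD2"), CD1 = "CE1", CD2 = "CE2",
           CE1 = "CZ", CE2 = "CZ"),
  P = list(CB = "CG", CG = "CD"),
  S = list(CB = "OG"),
  T = list(CB = c("OG1", "CG2")),
  W = list(CB = "CG", CG = c("CD1", "CD2"), CD1 = "NE1", NE1 = "CE2",
           CD2 = c("CE2", "CE3"), CE2 = "CZ2", CE3 = "CZ3", CZ2 = "CH2",
           CZ3 = "CH2"),
  Y = list(CB = "CG", CG = c("CD1", "CD2"), CD1 = "CE1", CD2 = "CE2",
           CE1 = "CZ", CE2 = "CZ", CZ = "OH"),
  V = list(CB = c("CG1", "CG2"))
)

topo_channels <- function(aa) {
  g <- sidechain_graphs[[aa]]
  atoms <- unique(c(names(g), unlist(g)))
  if (length(atoms) == 0) return(c(atoms = 0, compact = 0))
  # undirected adjacency, rooted at CB (bonded to the backbone C-alpha)
  adj <- setNames(vector("list", length(atoms)), atoms)
  for (a in names(g)) for (b in g[[a]]) {
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dist <- setNames(rep(Inf, length(atoms)), atoms)
  dist["CB"] <- 1  # CB is one side-chain atom from the backbone
  queue <- "CB"
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    for (b in adj[[a]]) if (dist[b] > dist[a] + 1) {
      dist[b] <- dist[a] + 1; queue <- c(queue, b)
    }
  }
  c(atoms = length(atoms), compact = max(dist))
}

test_that("packaged encoding matches an independent topology recomputation", {
  tab <- encoding_table()
  expect_equal(nrow(tab), 20)
  expect_equal(sort(tab$aa), sort(names(sidechain_graphs)))
  for (aa in tab$aa) {
    ch <- topo_channels(aa)
    row <- tab[tab$aa == aa, ]
    expect_equal(row$sidechain_atoms, unname(ch["atoms"]),
                 info = paste("side-chain atoms of", aa))
    expect_equal(row$compactness, unname(ch["compact"]),
                 info = paste("compactness of", aa))
  }
})

test_that("charge and hydrophobicity channels carry their defining anchors", {
  tab <- encoding_table()
  ch <- function(aa, col) tab[[col]][tab$aa == aa]
  expect_equal(ch("H", "charge"), 0.5)
  expect_equal(ch("D", "charge"), -1)
  expect_equal(ch("E", "charge"), -1)
  expect_equal(ch("K", "charge"), 1)
  expect_equal(ch("R", "charge"), 1)
  expect_true(all(tab$charge[!tab$aa %in% c("H", "D", "E", "K", "R")] == 0))
  expect_equal(ch("G", "sidechain_atoms"), 0)
  # Eisenberg consensus: Ile most hydrophobic, Arg least
  expect_equal(tab$aa[which.max(tab$hydrophobicity)], "I")
  expect_equal(tab$aa[which.min(tab$hydrophobicity)], "R")
})

test_that("residue encoding returns the four channels in order", {
  expect_equal(unname(encode_residue("H"))[3], 0.5)
  expect_equal(unname(encode_residue("G"))[1], 0)
  expect_equal(unname(encode_residue("-")), c(0, 0, 0, 0))
  expect_equal(unname(encode_residue(NA_character_)), c(0, 0, 0, 0))
  expect_error(encode_residue("B"), "Unknown amino-acid code")
  w <- encoding_table()[encoding_table()$aa == "W", ]
  expect_equal(unname(encode_residue("W")),
               c(w$sidechain_atoms, w$compactness, w$charge,
                 w$hydrophobicity))
})

test_that("schema lengths follow 4 x positions (+3 loop lengths)", {
  expect_equal(feature_schema("gbr1")$length, 52)
  expect_equal(feature_schema("gbr2")$length, 55)
  expect_equal(feature_schema("gbr3")$length, 148)
  expect_equal(feature_schema("gbr4")$length, 151)
  expect_equal(length(feature_schema("gbr1")$positions), 13)
  expect_equal(length(feature_schema("gbr4")$positions), 37)
  expect_true(all(feature_schema("gbr1")$positions %in%
                    feature_schema("gbr3")$positions))
})

test_that("loop lengths count occupied positions, insertions included", {
  fv <- make_fv_fixture(cdr_h3_length = 8)
  expect_equal(loop_lengths(fv), c(l1 = 11L, h2 = 9L, h3 = 8L))
  fv9 <- make_fv_fixture(cdr_h3_length = 9)  # adds H100A
  expect_equal(loop_lengths(fv9)[["h3"]], 9L)
  # no residues in a range -> zero
  bare <- fv_structure("bare", dplyr::bind_rows(res_row("L", 50),
                                                res_row("H", 10)))
  expect_equal(loop_lengths(bare), c(l1 = 0L, h2 = 0L, h3 = 0L))
})

test_that("featurization is pure and fixed-length under gaps", {
  fv <- make_fv_fixture(cdr_h3_length = 8)
  v1 <- featurize(fv, "gbr4")
  v2 <- featurize(fv, "gbr4")
  expect_identical(v1, v2)
  expect_length(v1, 151)
  # H100A..H100G unoccupied: seven gap blocks of four zeros
  gap_cols <- as.vector(vapply(paste0("H100", LETTERS[1:7]),
                               function(p) paste0(p, ".", c("atoms", "compact",
                                                            "charge", "hydro")),
                               character(4)))
  expect_true(all(v1[gap_cols] == 0))
})

test_that("positions outside the schema do not affect the vector", {
  fv_a <- make_fv_fixture(mutations = c(L10 = "W"))
  fv_b <- make_fv_fixture(mutations = c(L10 = "D"))  # L10 in no schema
  expect_identical(featurize(fv_a, "gbr4"), featurize(fv_b, "gbr4"))
  fv_c <- make_fv_fixture(mutations = c(L38 = "W"))
  expect_false(identical(featurize(fv_a, "gbr4"), featurize(fv_c, "gbr4")))
})

test_that("numbered-sequence files featurize like structures", {
  fv <- make_fv_fixture()
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# numbered sequence",
               paste(fv$residues$key, fv$residues$aa)), tf)
  seq_tab <- read_numbered_sequence(tf)
  expect_equal(nrow(seq_tab), nrow(fv$residues))
  expect_identical(featurize(tf, "gbr4"), featurize(fv, "gbr4"))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("L38 Q extra", bad)
  expect_error(read_numbered_sequence(bad), "Malformed")
})
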