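test_that("PDB round trip preserves coordinates to format precision", {
  st <- gen_ring_structure(simulation_config(seed = 2))
  tmp <- tempfile(fileext = ".pdb")
  write_structure(st$model, tmp)
  back <- read_structure(tmp)
  expect_equal(nrow(back$atoms), nrow(st$model$atoms))
  expect_equal(nrow(back$metals), 2L)
  a <- st$model$atoms[order(st$model$atoms$chain, st$model$atoms$resno,
                            st$model$atoms$atom), ]
  b <- back$atoms[order(back$atoms$chain, back$atoms$resno, back$atoms$atom), ]
  expect_equal(as.matrix(b[, c("x", "y", "z")]),
               as.matrix(a[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # second round trip is exact: values already quantized to 3 decimals
  tmp2 <- tempfile(fileext = ".pdb")
  write_structure(back, tmp2)
  expect_identical(read_structure(tmp2)$atoms, back$atoms)
})

test_that("altlocs resolve by occupancy then file order; insertions rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "A", "ALA", "A", 1, " ", 0, 0, 0, 0.4),
    pdb_line(2, "CA", "B", "ALA", "A", 1, " ", 9, 9, 9, 0.6),
    pdb_line(3, "CA", " ", "GLY", "A", 2, " ", 1, 1, 1, 1.0),
    pdb_line(4, "CB", "A", "GLY", "A", 2, " ", 2, 2, 2, 0.5),
    pdb_line(5, "CB", "B", "GLY", "A", 2, " ", 7, 7, 7, 0.5),
    pdb_line(6, "ZN", " ", "ZN", "A", 99, " ", 5, 5, 5, 1.0, type = "HETATM"),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)            # one atom kept per name
  expect_equal(m$atoms$x[m$atoms$resno == 1], 9)   # higher occupancy wins
  expect_equal(m$atoms$x[m$atoms$resno == 2 & m$atoms$atom == "CB"], 2)
  expect_equal(nrow(m$metals), 1L)           # zinc HETATM -> metals
  g <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", " ", "ALA", "A", 1, "A", 0, 0, 0, 1), "END"),
             g)
  expect_error(read_structure(g), "insertion")
})

test_that("kabsch recovers constructed rigid motions exactly", {
  set.seed(42)
  X <- matrix(rnorm(30), 10, 3)
  sp0 <- kabsch_superpose(X, X)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  th <- pi / 2
  Rz <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  Y <- sweep(X %*% Rz, 2, c(3, -1, 2), `+`)
  sp <- kabsch_superpose(X, Y)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(sp, X), Y, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kabsch RMSD is minimal: below sampled transforms, equal to optimizer", {
  set.seed(99)
  for (i in 1:10) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    sp <- kabsch_superpose(A, B)
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    sampled <- vapply(1:200, function(k) {
      sqrt(mean(rowSums((Ac %*% random_rotation() - Bc)^2)))
    }, 0)
    expect_true(all(sp$rmsd <= sampled + 1e-12))
    expect_equal(sp$rmsd, oracle_min_rmsd(A, B), tolerance = 1e-6)
  }
})

test_that("superposing already-superposed coordinates is the identity", {
  set.seed(5)
  A <- matrix(rnorm(24), 8, 3); B <- matrix(rnorm(24), 8, 3)
  sp <- kabsch_superpose(A, B)
  A2 <- apply_superposition(sp, A)
  sp2 <- kabsch_superpose(A2, B)
  expect_equal(sp2$rotation, diag(3), tolerance = 1e-8)
  expect_equal(sp2$rmsd, sp$rmsd, tolerance = 1e-10)
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3, 3),
                                matrix(rnorm(12), 4, 3)), "equal-size")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, matrix(rnorm(15), 5, 3)), "collinear")
})

test_that("interface boundary is inclusive and partner forms agree", {
  atoms <- data.frame(
    chain = c("A", "A", "B"), resno = c(1L, 2L, 1L),
    resname = c("ALA", "ALA", "GLY"), atom = "CA",
    x = c(0, 0, 0), y = c(0, 0, 0), z = c(4.9, 5.1, 0))
  m <- structure_model(atoms[atoms$chain == "A", ])
  p <- structure_model(atoms[atoms$chain == "B", ])
  rep1 <- interface_residues(m, p, cutoff = 5.0)
  expect_equal(rep1$resno, 1L)
  expect_equal(rep1$min_distance, 4.9)
  both <- structure_model(atoms)
  rep2 <- interface_residues(both, "B", cutoff = 5.0)
  expect_equal(as.data.frame(rep2), as.data.frame(rep1))
  empty <- interface_residues(m, structure_model(atoms[0, ]), cutoff = 5.0)
  expect_equal(nrow(empty), 0L)
})

test_that("interface caller equals brute-force scan; monotone in cutoff", {
  set.seed(123)
  a <- random_chain(50, "A")
  b <- random_chain(50, "B", origin = c(10, 0, 0))
  m <- structure_model(a); p <- structure_model(b)
  for (cutoff in c(4, 5, 8)) {
    got <- interface_residues(m, p, cutoff = cutoff)
    want <- oracle_interface(a, b, cutoff)
    expect_equal(got$resno, want$resno)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
  }
  narrow <- interface_residues(m, p, cutoff = 4)$resno
  wide <- interface_residues(m, p, cutoff = 8)$resno
  expect_true(all(narrow %in% wide))
})

test_that("exposure proxy matches neighbor recount and saturates at the cap", {
  lone <- structure_model(data.frame(chain = "A", resno = 1L, resname = "GLY",
                                     atom = "CA", x = 0, y = 0, z = 0))
  expect_equal(exposure_score(lone, "A", 1L), 1)
  # 30 CAs packed around residue 1: cap saturation -> fully buried
  n <- 31
  cl <- data.frame(chain = "A", resno = seq_len(n), resname = "GLY",
                   atom = "CA", x = c(0, rnorm(n - 1, 0, 2)),
                   y = c(0, rnorm(n - 1, 0, 2)), z = c(0, rnorm(n - 1, 0, 2)))
  dense <- structure_model(cl)
  expect_equal(exposure_score(dense, "A", 1L), 0)
  set.seed(8)
  ch <- random_chain(25)
  m <- structure_model(ch)
  for (r in c(1L, 12L, 25L)) {
    d <- sqrt((ch$x - ch$x[r])^2 + (ch$y - ch$y[r])^2 + (ch$z - ch$z[r])^2)
    nb <- sum(d <= 10) - 1L
    expect_equal(exposure_score(m, "A", r), 1 - min(nb, 20) / 20)
  }
  expect_error(exposure_score(m, "A", 999L), "no CA")
})

test_that("zinc geometry check flags displaced ligands and reports raw distances", {
  st <- gen_ring_structure(simulation_config(seed = 4,
                                             structure = list(jitter_sd = 0)))
  rep0 <- zinc_geometry_check(st$model, st$ligand_resnos)
  expect_true(all(rep0$pass))
  expect_equal(rep0$distance, rep(2.3, 8), tolerance = 1e-9)
  # displace one SG to 4 A from its zinc
  m <- st$model
  i <- which(m$atoms$chain == "A" & m$atoms$resno == 1 & m$atoms$atom == "SG")
  zn1 <- as.numeric(m$atoms[i, c("x", "y", "z")]) / 2.3 * 4
  m$atoms[i, c("x", "y", "z")] <- zn1
  rep1 <- zinc_geometry_check(m, st$ligand_resnos)
  expect_equal(sum(!rep1$pass), 1L)
  expect_equal(rep1$resno[!rep1$pass], 1L)
  # distances equal recomputation from raw coordinates
  zn <- as.matrix(st$model$metals[, c("x", "y", "z")])
  for (k in seq_len(nrow(rep0))) {
    sg <- st$model$atoms[st$model$atoms$resno == rep0$resno[k] &
                           st$model$atoms$atom == "SG" &
                           st$model$atoms$chain == "A", c("x", "y", "z")]
    d <- min(sqrt(rowSums(sweep(zn, 2, as.numeric(sg))^2)))
    expect_equal(rep0$distance[k], d, tolerance = 1e-9)
  }
  nozinc <- structure_model(st$model$atoms)
  expect_error(zinc_geometry_check(nozinc, st$ligand_resnos), "fewer than 2")
})

test_that("threading copies template CAs, flags insertions, keeps metals", {
  tpl_seq <- "ACDEFGHIKL"
  tpl <- line_structure(tpl_seq, metals = data.frame(elem = "ZN", x = 0,
                                                     y = 0, z = 0))
  tpl$metals <- rbind(tpl$metals, data.frame(elem = "ZN", x = 9, y = 0, z = 0))
  q_same <- protein_sequence("q", tpl_seq)
  aln <- pairwise_global_align(q_same, protein_sequence("t", tpl_seq))
  thr <- thread_model(q_same, tpl, aln)
  expect_equal(unname(ca_coords(thr)), unname(ca_coords(tpl)))
  expect_length(attr(thr, "unmodeled"), 0L)
  expect_equal(nrow(thr$metals), 2L)
  # two-residue insertion in the query -> exactly two unmodeled residues
  q_ins <- protein_sequence("qi", "ACDEFWWGHIKL")
  aln2 <- pairwise_global_align(q_ins, protein_sequence("t", tpl_seq))
  thr2 <- thread_model(q_ins, tpl, aln2)
  expect_length(attr(thr2, "unmodeled"), 2L)
  # modeled positions inherit template CAs in alignment order, so the
  # model-vs-template RMSD over aligned positions is zero by construction
  expect_equal(unname(ca_coords(thr2)), unname(ca_coords(tpl)))
  sp <- kabsch_superpose(ca_coords(thr2), ca_coords(tpl))
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
})

test_that("template ranking is faithful to the score formula and input order", {
  qcfg <- simulation_config(seed = 9)
  sq <- gen_ring_sequence(qcfg)
  query <- list(sequence = sq$sequence, assignment = sq$assignment)
  gq <- diff(sq$positions) - 1L
  mk <- function(id, seqstr, gaps) {
    list(id = id, sequence = seqstr,
         ligand_positions = cumsum(c(1L, gaps + 1L)))
  }
  set.seed(10)
  bg <- function(n) paste(sample(c("G", "S", "T", "V"), n, TRUE), collapse = "")
  templates <- list(
    mk("T_exact", sq$sequence$residues, gq),
    mk("T_revgap", sq$sequence$residues, rev(gq)),
    mk("T_near", chartr("A", "G", sq$sequence$residues), gq + c(0, 1, 0, 0, 0, 1, 0)),
    mk("T_far", bg(nchar(sq$sequence$residues)), rep(3L, 7)))
  rk <- rank_templates(query, templates)
  expect_equal(rk$template_id[1], "T_exact")
  expect_equal(rk$spacing_compatibility[rk$template_id == "T_exact"], 1)
  # reversed gap vector scores below the exact-gap template
  expect_lt(rk$spacing_compatibility[rk$template_id == "T_revgap"],
            rk$spacing_compatibility[rk$template_id == "T_exact"])
  # independent recomputation of every component and the combined score
  for (t in templates) {
    aln <- pairwise_global_align(sq$sequence, t$sequence)
    ca <- strsplit(aln$aligned_a, "")[[1]]; cb <- strsplit(aln$aligned_b, "")[[1]]
    ident <- 100 * sum(ca == cb & ca != "-") / length(ca)
    expect_equal(rk$percent_identity[rk$template_id == t$id], ident)
    good <- mapply(function(x, y) x != "-" && y != "-" &&
                     (x == y || blosum62[x, y] > 0), ca, cb)
    run <- rle(as.logical(good))
    expect_equal(rk$longest_contiguous_block[rk$template_id == t$id],
                 max(c(0, run$lengths[run$values])))
    gt <- diff(t$ligand_positions) - 1L
    expect_equal(rk$spacing_compatibility[rk$template_id == t$id],
                 max(0, 1 - sum(abs(gq - gt)) / sum(gq + gt)))
  }
  scale01 <- function(x) if (diff(range(x)) < 1e-12) rep(1, length(x))
                         else (x - min(x)) / diff(range(x))
  comb <- (scale01(rk$percent_identity) + scale01(rk$longest_contiguous_block) +
             scale01(rk$spacing_compatibility)) / 3
  expect_equal(rk$combined, comb, tolerance = 1e-12)
  # invariant to template input order
  rk2 <- rank_templates(query, rev(templates))
  expect_equal(rk2, rk)
  expect_warning(
    rank_templates(query, c(templates, list(list(id = "T_bad",
                                                 sequence = "AAAA")))),
    "ligand annotation")
})
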