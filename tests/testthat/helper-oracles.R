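# Independent brute-force oracles and small fixture builders shared across
# the test files.  Each oracle re-derives the quantity from first principles,
# without calling the implementation path it checks.

# exhaustive ligand-slot enumeration: every size-k subset of candidate
# positions, checked slot-by-slot against the spacing model
oracle_scan <- function(seq, model = spacing_model()) {
  letters <- strsplit(seq$residues, "")[[1]]
  pos <- seq$offset + seq_along(letters) - 1L
  k <- model$ligand_count
  union_allowed <- unique(unlist(model$slot_residues))
  cand <- pos[letters %in% union_allowed]
  if (length(cand) < k) return(list())
  combos <- utils::combn(cand, k, simplify = FALSE)
  ok <- Filter(function(p) {
    res <- letters[p - seq$offset + 1L]
    if (!all(mapply(function(r, allowed) r %in% allowed,
                    res, model$slot_residues)))
      return(FALSE)
    g <- diff(p) - 1L
    all(g >= model$gap_ranges[, 1L] & g <= model$gap_ranges[, 2L])
  }, combos)
  ok
}

position_signatures <- function(assignments) {
  sort(vapply(assignments, function(a) {
    p <- if (inherits(a, "ligand_assignment")) a$positions else a
    paste(p, collapse = ",")
  }, ""))
}

# exhaustive global-alignment score: enumerate every monotone alignment path,
# affine gap cost open + L * ext per gap run
oracle_align_score <- function(sa, sb, submat, open = 10, ext = 0.5) {
  A <- strsplit(sa, "")[[1]]; B <- strsplit(sb, "")[[1]]
  n <- length(A); m <- length(B)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i == n && j == m) { best <<- max(best, score); return(invisible()) }
    if (i < n && j < m)
      rec(i + 1L, j + 1L, score + submat[A[i + 1L], B[j + 1L]], "M")
    if (j < m)
      rec(i, j + 1L, score - (if (last == "A") ext else open + ext), "A")
    if (i < n)
      rec(i + 1L, j, score - (if (last == "B") ext else open + ext), "B")
  }
  rec(0L, 0L, 0, "M")
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# rotation matrix from an axis-angle vector (Rodrigues)
rot_from_vec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  a <- v / th
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() rot_from_vec(stats::rnorm(3))

# numerical-minimization oracle for the optimal superposition RMSD:
# multi-start BFGS over axis-angle rotations of the centred mobile set
oracle_min_rmsd <- function(mobile, target, n_starts = 8L) {
  M <- sweep(mobile, 2, colMeans(mobile))
  Tm <- sweep(target, 2, colMeans(target))
  obj <- function(v) sqrt(mean(rowSums((M %*% rot_from_vec(v) - Tm)^2)))
  starts <- c(list(rep(0, 3)),
              lapply(seq_len(n_starts - 1L), function(i) stats::rnorm(3)))
  min(vapply(starts, function(s) {
    stats::optim(s, obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))$value
  }, 0))
}

# all-pairs O(n^2) interface scan with explicit loops
oracle_interface <- function(subj_atoms, part_atoms, cutoff) {
  keys <- unique(paste(subj_atoms$chain, subj_atoms$resno))
  hits <- data.frame(chain = character(), resno = integer(),
                     min_distance = numeric())
  for (k in keys) {
    sel <- paste(subj_atoms$chain, subj_atoms$resno) == k
    a <- subj_atoms[sel, , drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(part_atoms))) {
      d <- sqrt((a$x[i] - part_atoms$x[j])^2 + (a$y[i] - part_atoms$y[j])^2 +
                (a$z[i] - part_atoms$z[j])^2)
      dmin <- min(dmin, d)
    }
    if (dmin <= cutoff)
      hits <- rbind(hits, data.frame(chain = a$chain[1], resno = a$resno[1],
                                     min_distance = dmin))
  }
  hits[order(hits$chain, hits$resno), , drop = FALSE]
}

# random CA-only chain along a jittered path
random_chain <- function(n, chain = "A", origin = c(0, 0, 0), step = 3.8) {
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- origin
  for (i in seq_len(n - 1L))
    xyz[i + 1L, ] <- xyz[i, ] + step * {
      d <- stats::rnorm(3); d / sqrt(sum(d^2))
    }
  data.frame(chain = chain, resno = seq_len(n), resname = "GLY", atom = "CA",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# CA-only structure for a sequence: residues on a zig-zag trace (non-collinear
# so superposition onto it is well posed)
line_structure <- function(residues, chain = "A", z = 0, metals = NULL) {
  letters <- strsplit(residues, "")[[1]]
  i <- seq_along(letters)
  atoms <- data.frame(chain = chain, resno = i,
                      resname = vapply(letters, bio3d::aa123, ""),
                      atom = "CA", x = 3.8 * i, y = 1.5 * (i %% 2), z = z,
                      stringsAsFactors = FALSE)
  structure_model(atoms, metals)
}

# synthetic sequence with cysteines at the printed positions of the SPE-42
# C-terminal domain, all other residues alanine
spe42_toy_sequence <- function() {
  res <- rep("A", 60L)
  cys <- c(678L, 681L, 684L, 700L, 703L, 708L, 711L, 718L, 721L)
  res[cys - 670L + 1L] <- "C"
  protein_sequence("spe42_cterm", paste(res, collapse = ""), offset = 670L)
}

# template bundle for the structure pipeline: full-length template chain
# whose ligand residues sit at the toy zinc-site coordinates and whose
# sequence equals the query, plus the partner chain and both zincs
make_template_bundle <- function(seed = 1L, dir = tempfile("tpl")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- simulation_config(seed = seed, structure = list(jitter_sd = 0))
  sq <- gen_ring_sequence(cfg)
  st <- gen_ring_structure(cfg)
  letters <- strsplit(sq$sequence$residues, "")[[1]]
  lig_i <- sq$positions - sq$sequence$offset + 1L
  lig_ca <- st$model$atoms[st$model$atoms$chain == "A" &
                             st$model$atoms$atom == "CA", ]
  xyz <- cbind(x = 3.8 * seq_along(letters), y = -80, z = -80)
  xyz[lig_i, ] <- as.matrix(lig_ca[order(lig_ca$resno), c("x", "y", "z")])
  atoms <- data.frame(chain = "A", resno = seq_along(letters),
                      resname = vapply(letters, bio3d::aa123, ""),
                      atom = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  partner <- st$model$atoms[st$model$atoms$chain == "B", ]
  model <- structure_model(rbind(atoms, partner), st$model$metals)
  pdb <- file.path(dir, "template.pdb")
  write_structure(model, pdb)
  fasta <- file.path(dir, "query.fasta")
  write_fasta(sq$sequence, fasta)
  list(dir = dir, query_fasta = fasta, query = sq, structure = st,
       template = list(id = "TPL1", pdb = pdb,
                       sequence = sq$sequence$residues,
                       ligand_positions = lig_i,
                       template_chain = "A", partner_chain = "B"),
       # site-1 ligands (cross-brace slots 1,2,5,6) in query numbering
       planted_contacts = sq$positions[c(1L, 2L, 5L, 6L)])
}

# minimal hand-written PDB text (fixed-width records) for parser edge cases
pdb_line <- function(serial, name, alt, resn, chain, resno, icode,
                     x, y, z, occ, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, paste0(" ", name), alt, resn, chain, resno, icode,
          x, y, z, occ, 0)
}
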