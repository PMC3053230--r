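# Structure-level analysis: PDB ingestion into a light atom table, Kabsch
# superposition, template ranking, CA-level rigid threading, interface-residue
# calling, a neighbor-count exposure proxy and zinc-site geometry checks.

#' Structure model container
#'
#' Atom-table representation of a (possibly multi-chain) structure: one row
#' per atom with chain, residue number/name, atom name and coordinates in
#' Angstrom, plus a separate table of metal ions (here, the zinc centres of
#' RING domains).
#'
#' @param atoms `data.frame` with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z`.
#' @param metals Optional `data.frame` with columns `elem`, `x`, `y`, `z`.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, metals = NULL) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (is.null(metals))
    metals <- data.frame(elem = character(), x = numeric(), y = numeric(),
                         z = numeric())
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  for (ch in unique(atoms$chain)) {
    rn <- unique(atoms$resno[atoms$chain == ch])
    if (any(diff(rn) <= 0L))
      stop("residue numbers not strictly increasing in chain ", ch,
           call. = FALSE)
  }
  structure(list(atoms = atoms, metals = metals), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat(sprintf("<structure_model> %d atoms, %d metal(s); chains: %s\n",
              nrow(x$atoms), nrow(x$metals),
              paste(sprintf("%s (%d atoms)", names(ch), ch), collapse = ", ")))
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records with `bio3d::read.pdb`.  Alternate locations
#' are resolved per atom by highest occupancy, then file order; insertion
#' codes are rejected; zinc HETATMs populate the `metals` table and other
#' HETATMs (waters, buffers) are dropped.
#'
#' @param path PDB file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  p <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- p$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported", call. = FALSE)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  keep <- !duplicated(key[order(-occ)])[order(order(-occ))]
  # order(-occ) is stable, so ties resolve to first occurrence in the file
  at <- at[keep, , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]
  is_zn <- at$type == "HETATM" &
    (toupper(at$resid) == "ZN" | toupper(at$elety) == "ZN")
  metals <- data.frame(elem = rep("ZN", sum(is_zn)),
                       x = at$x[is_zn], y = at$y[is_zn], z = at$z[is_zn])
  body <- at[at$type == "ATOM", , drop = FALSE]
  atoms <- data.frame(chain = ifelse(is.na(body$chain), "A", body$chain),
                      resno = body$resno, resname = body$resid,
                      atom = body$elety,
                      x = body$x, y = body$y, z = body$z,
                      stringsAsFactors = FALSE)
  structure_model(atoms, metals)
}

#' Write a structure model to PDB
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  m <- model$metals
  n <- nrow(a); k <- nrow(m)
  xyz <- c(t(as.matrix(rbind(a[, c("x", "y", "z")],
                             stats::setNames(m[, c("x", "y", "z")],
                                             c("x", "y", "z"))))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = c(rep("ATOM", n), rep("HETATM", k)),
    resno = c(a$resno, seq_len(k) + 9000L),
    resid = c(a$resname, rep("ZN", k)),
    eleno = seq_len(n + k),
    elety = c(a$atom, rep("ZN", k)),
    chain = c(a$chain, rep("Z", k)),
    o = rep(1, n + k), b = rep(0, n + k))
  invisible(path)
}

atom_coords <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' CA coordinates of a chain
#'
#' @param model A [structure_model()].
#' @param chain Chain id; default first chain.
#' @return Numeric matrix (n x 3) with residue numbers as rownames.
#' @export
ca_coords <- function(model, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  out <- as.matrix(a[, c("x", "y", "z")])
  rownames(out) <- a$resno
  out
}

#' Kabsch least-squares rigid superposition
#'
#' Optimal rotation and translation (reflections excluded) minimizing the
#' RMSD between two paired point sets, computed by singular value
#' decomposition of the cross-covariance of the centred coordinates.  The
#' transform maps `mobile` onto `target`: for row-vector coordinates,
#' `transformed = mobile %*% rotation + translation`.
#'
#' @param mobile,target Numeric n x 3 matrices of paired coordinates, n >= 3.
#' @param paired_residues Optional record of the residue-number pairing.
#' @return Object of class `superposition` with `rotation` (det +1),
#'   `translation`, `rmsd` and `paired_residues`.
#' @export
kabsch_superpose <- function(mobile, target, paired_residues = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 paired points", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2L, cm); Tm <- sweep(target, 2L, ct)
  for (X in list(M, Tm)) {
    sv <- svd(X)$d
    if (sv[2L] <= 1e-8 * max(sv[1L], 1e-12))
      stop("degenerate (collinear) point set", call. = FALSE)
  }
  H <- crossprod(M, Tm)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((M %*% R - Tm)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - cm %*% R),
                 rmsd = rmsd, paired_residues = paired_residues),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.4f A over %s points\n", x$rmsd,
              if (is.null(x$paired_residues)) "paired"
              else nrow(x$paired_residues)))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param coords n x 3 matrix (or a [structure_model()], transformed in
#'   place including metals).
#' @export
apply_superposition <- function(sp, coords) {
  tf <- function(m) sweep(as.matrix(m) %*% sp$rotation, 2L, sp$translation, `+`)
  if (inherits(coords, "structure_model")) {
    xyz <- tf(coords$atoms[, c("x", "y", "z")])
    coords$atoms[, c("x", "y", "z")] <- xyz
    if (nrow(coords$metals)) {
      mm <- tf(coords$metals[, c("x", "y", "z")])
      coords$metals[, c("x", "y", "z")] <- mm
    }
    return(coords)
  }
  tf(coords)
}

longest_block <- function(ca, cb, submat) {
  both <- ca != "-" & cb != "-"
  good <- rep(FALSE, length(ca))
  if (any(both))
    good[both] <- ca[both] == cb[both] | submat[cbind(ca[both], cb[both])] > 0
  if (!any(good)) return(0L)
  r <- rle(good)
  max(r$lengths[r$values])
}

spacing_compatibility <- function(gq, gt) {
  if (length(gq) != length(gt)) return(0)
  denom <- sum(gq + gt)
  if (denom == 0) return(1)
  max(0, 1 - sum(abs(gq - gt)) / denom)
}

minmax_scale <- function(x) {
  if (length(x) == 0L) return(x)
  r <- range(x)
  if (r[2L] - r[1L] < .Machine$double.eps) return(rep(1, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Rank candidate template structures for modelling
#'
#' Scores each annotated template against the query by the three criteria
#' used for RING-domain template selection: overall percent identity from a
#' global alignment, the longest contiguous block of identical-or-similar
#' aligned columns, and compatibility of the inter-ligand spacing vectors
#' (1 minus the L1 distance between gap vectors, normalized by their total).
#' The combined score is a weighted mean of the three components after
#' min-max scaling across templates; ties break by template id.
#'
#' @param query List with `sequence` (a [protein_sequence()]) and
#'   `assignment` (a `ligand_assignment` or integer positions).
#' @param templates List of templates, each a list with `id`, `sequence`
#'   (string or [protein_sequence()]) and `ligand_positions`; templates
#'   lacking ligand annotation are excluded with a warning.
#' @param weights Length-3 non-negative weights for identity, contiguity and
#'   spacing (default equal).
#' @return `data.frame` of class `template_ranking`, best template first.
#' @export
rank_templates <- function(query, templates, weights = c(1, 1, 1)) {
  stopifnot(inherits(query$sequence, "protein_sequence"))
  qpos <- if (inherits(query$assignment, "ligand_assignment"))
    query$assignment$positions else as.integer(query$assignment)
  gq <- diff(qpos) - 1L
  ok <- vapply(templates, function(t) !is.null(t$ligand_positions), TRUE)
  if (any(!ok)) {
    bad <- vapply(templates[!ok], function(t) t$id %||% "<unnamed>", "")
    warning("excluding templates without ligand annotation: ",
            paste(bad, collapse = ", "), call. = FALSE)
    templates <- templates[ok]
  }
  if (length(templates) == 0L) stop("no usable templates", call. = FALSE)
  rows <- lapply(templates, function(t) {
    tseq <- if (inherits(t$sequence, "protein_sequence")) t$sequence
            else protein_sequence(t$id, t$sequence)
    aln <- pairwise_global_align(query$sequence, tseq)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    data.frame(template_id = t$id,
               percent_identity = aln$report$percent_identity,
               longest_contiguous_block = longest_block(ca, cb, aln$submat),
               spacing_compatibility =
                 spacing_compatibility(gq, diff(as.integer(t$ligand_positions)) - 1L),
               stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  w <- weights / sum(weights)
  comp <- cbind(minmax_scale(sc$percent_identity),
                minmax_scale(sc$longest_contiguous_block),
                minmax_scale(sc$spacing_compatibility))
  sc$combined <- as.numeric(comp %*% w)
  sc <- sc[order(-sc$combined, sc$template_id), , drop = FALSE]
  rownames(sc) <- NULL
  class(sc) <- c("template_ranking", "data.frame")
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thread a query sequence onto a template backbone
#'
#' CA-level rigid threading: each query residue aligned to a template residue
#' inherits that residue's CA coordinate; query residues aligned to gaps are
#' left unmodeled (recorded in the `unmodeled` attribute); template metals are
#' copied through.  This deliberately replaces restraint-based all-atom
#' homology modelling: the downstream interface and exposure analyses operate
#' on CA/heavy-atom geometry only.
#'
#' @param query A [protein_sequence()].
#' @param template A [structure_model()] whose `template_chain` residues
#'   correspond one-to-one with the aligned template sequence.
#' @param aln A `pairwise_alignment` of query (first) vs template sequence
#'   (second).
#' @param template_chain Chain id in `template`; default first chain.
#' @return A [structure_model()] (chain "A", CA atoms only) with attribute
#'   `unmodeled` giving unmodeled query positions.
#' @export
thread_model <- function(query, template, aln, template_chain = NULL) {
  stopifnot(inherits(query, "protein_sequence"),
            inherits(template, "structure_model"),
            inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  if (length(ca) == 0L) stop("empty alignment", call. = FALSE)
  tca <- ca_coords(template, template_chain)
  tlen <- sum(cb != "-")
  if (nrow(tca) < tlen)
    stop("alignment references residues absent from template chain",
         call. = FALSE)
  qi <- cumsum(ca != "-")
  ti <- cumsum(cb != "-")
  modeled <- ca != "-" & cb != "-"
  unmodeled_pos <- query$offset + qi[ca != "-" & cb == "-"] - 1L
  pos <- query$offset + qi[modeled] - 1L
  xyz <- tca[ti[modeled], , drop = FALSE]
  resname <- vapply(ca[modeled], function(r) bio3d::aa123(r), "")
  atoms <- data.frame(chain = "A", resno = pos, resname = resname,
                      atom = "CA",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  out <- structure_model(atoms, metals = template$metals)
  attr(out, "unmodeled") <- unmodeled_pos
  out
}

pairwise_sq_dists <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
}

is_hydrogen <- function(atom_names) grepl("^[0-9]*H", atom_names)

#' Interface residues within a distance cutoff of a partner
#'
#' A residue is reported iff the minimum distance between any of its heavy
#' atoms and any heavy atom of the partner is less than or equal to the
#' cutoff (inclusive boundary) — the criterion used to call the putative
#' E2-binding surface of a RING domain from a superposed complex.
#'
#' @param model A [structure_model()] (the chain(s) being reported on).
#' @param partner A [structure_model()], or a chain id within `model` (in
#'   which case the remaining chains are reported against that chain).
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return `data.frame` of class `interface_report` (chain, resno, resname,
#'   min_distance), sorted by chain then residue number; attribute `cutoff`.
#' @export
interface_residues <- function(model, partner, cutoff = 5.0) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  if (is.character(partner) && length(partner) == 1L) {
    part_atoms <- model$atoms[model$atoms$chain == partner, , drop = FALSE]
    subj_atoms <- model$atoms[model$atoms$chain != partner, , drop = FALSE]
  } else {
    stopifnot(inherits(partner, "structure_model"))
    part_atoms <- partner$atoms
    subj_atoms <- model$atoms
  }
  part_atoms <- part_atoms[!is_hydrogen(part_atoms$atom), , drop = FALSE]
  subj_atoms <- subj_atoms[!is_hydrogen(subj_atoms$atom), , drop = FALSE]
  empty <- data.frame(chain = character(), resno = integer(),
                      resname = character(), min_distance = numeric())
  if (nrow(part_atoms) == 0L || nrow(subj_atoms) == 0L) {
    class(empty) <- c("interface_report", "data.frame")
    attr(empty, "cutoff") <- cutoff
    return(empty)
  }
  d2 <- pairwise_sq_dists(as.matrix(subj_atoms[, c("x", "y", "z")]),
                          as.matrix(part_atoms[, c("x", "y", "z")]))
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  key <- paste(subj_atoms$chain, subj_atoms$resno, sep = "|")
  res_min <- tapply(mind, key, min)
  first <- !duplicated(key)
  info <- subj_atoms[first, c("chain", "resno", "resname"), drop = FALSE]
  info$min_distance <- as.numeric(res_min[paste(info$chain, info$resno,
                                                sep = "|")])
  hit <- info[info$min_distance <= cutoff, , drop = FALSE]
  hit <- hit[order(hit$chain, hit$resno), , drop = FALSE]
  rownames(hit) <- NULL
  class(hit) <- c("interface_report", "data.frame")
  attr(hit, "cutoff") <- cutoff
  hit
}

#' Solvent-exposure proxy from CA neighbor counts
#'
#' Buried residues sit in dense CA neighborhoods; the score is
#' `1 - min(neighbors, cap) / cap` where neighbors counts other CA atoms
#' within `radius` of the residue's CA.  1 means fully exposed, 0 buried.
#'
#' @param model A [structure_model()].
#' @param chain,resno Residue to score.
#' @param radius Neighborhood radius in Angstrom (default 10).
#' @param cap Neighbor count treated as fully buried (default 20).
#' @return Numeric in `[0, 1]`.
#' @export
exposure_score <- function(model, chain, resno, radius = 10, cap = 20) {
  a <- model$atoms
  self <- a$chain == chain & a$resno == resno & a$atom == "CA"
  if (!any(self)) stop("residue has no CA atom", call. = FALSE)
  p <- as.matrix(a[self, c("x", "y", "z")])[1L, , drop = FALSE]
  cas <- a[a$atom == "CA" & !self, , drop = FALSE]
  if (nrow(cas) == 0L) return(1)
  d2 <- pairwise_sq_dists(as.matrix(cas[, c("x", "y", "z")]), p)
  nb <- sum(d2 <= radius^2)
  1 - min(nb, cap) / cap
}

#' Check zinc-site coordination geometry
#'
#' For each of the two zinc centres of a RING domain, reports the distance
#' from each assigned ligand residue's sulfur atom (SG, falling back to CA
#' when no sulfur is present) to its zinc, and flags ligands whose Zn-S
#' distance falls outside the accepted coordination range.  Ligands are
#' partitioned over the zincs in the cross-brace arrangement (slots 1,2,5,6
#' vs 3,4,7,8) and each partition half is matched to the nearer zinc.
#'
#' @param model A [structure_model()] with at least two zinc metals.
#' @param assignment A `ligand_assignment` or integer vector of 8 residue
#'   numbers.
#' @param chain Chain holding the ligand residues; default first chain.
#' @param srange Accepted Zn-S distance range in Angstrom, default
#'   `c(1.8, 3.0)`.
#' @return `data.frame` (site, resno, atom, distance, pass) of class
#'   `zinc_report`.
#' @export
zinc_geometry_check <- function(model, assignment, chain = NULL,
                                srange = c(1.8, 3.0)) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$metals) < 2L)
    stop("model has fewer than 2 zinc ions", call. = FALSE)
  pos <- if (inherits(assignment, "ligand_assignment")) assignment$positions
         else as.integer(assignment)
  stopifnot(length(pos) == 8L)
  if (is.null(chain)) chain <- model$atoms$chain[1L]
  part <- cross_brace_partition(pos)
  zn <- as.matrix(model$metals[, c("x", "y", "z")])
  ligand_atom <- function(p) {
    a <- model$atoms[model$atoms$chain == chain & model$atoms$resno == p, ,
                     drop = FALSE]
    if (nrow(a) == 0L) stop("assigned residue ", p, " absent from model",
                            call. = FALSE)
    s <- a[a$atom %in% c("SG", "S"), , drop = FALSE]
    if (nrow(s)) s[1L, ] else a[a$atom == "CA", , drop = FALSE][1L, ]
  }
  half_dists <- function(half, zi) {
    vapply(half, function(p) {
      at <- ligand_atom(p)
      sqrt(sum((c(at$x, at$y, at$z) - zn[zi, ])^2))
    }, 0)
  }
  # match partition halves to zincs by total ligand distance
  cost <- function(z1, z2) sum(half_dists(part$zn1, z1)) +
                           sum(half_dists(part$zn2, z2))
  assign12 <- cost(1L, 2L) <= cost(2L, 1L)
  zidx <- if (assign12) c(1L, 2L) else c(2L, 1L)
  out <- do.call(rbind, lapply(1:2, function(site) {
    half <- part[[site]]
    d <- half_dists(half, zidx[site])
    atom <- vapply(half, function(p) ligand_atom(p)$atom, "")
    data.frame(site = site, resno = half, atom = atom, distance = d,
               pass = d >= srange[1L] & d <= srange[2L])
  }))
  rownames(out) <- NULL
  class(out) <- c("zinc_report", "data.frame")
  out
}

#' Write an interface report to TSV or JSON
#'
#' @param report An `interface_report`.
#' @param path Output file; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @export
write_interface_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(cutoff = attr(report, "cutoff"),
                              residues = as.data.frame(report)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
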