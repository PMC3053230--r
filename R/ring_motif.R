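# Sequence-level RING-finger analysis: protein sequences with author
# numbering, spacing models for the zinc-ligand slots, the constraint scanner,
# and pairwise divergence statistics.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Protein sequence with a numbering offset
#'
#' A light container for a one-letter amino-acid sequence together with the
#' residue number assigned to its first residue, so that published positions
#' (e.g. C678 in the SPE-42 C-terminal domain) map onto the stored string
#' without renumbering.
#'
#' @param id Sequence identifier.
#' @param residues One-letter amino-acid string (20 standard letters plus X).
#' @param offset Integer residue number of the first residue (default 1).
#' @return An object of class `protein_sequence` with fields `id`, `residues`
#'   and `offset`.
#' @examples
#' ps <- protein_sequence("toy", "MCACAC", offset = 10)
#' residue_at(ps, 11)
#' @export
protein_sequence <- function(id, residues, offset = 1L) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("empty sequence", call. = FALSE)
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letters: ", paste(bad, collapse = ", "), call. = FALSE)
  offset <- as.integer(offset)
  stopifnot(length(offset) == 1L, !is.na(offset))
  structure(list(id = id, residues = residues, offset = offset),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d aa, residues numbered %d..%d\n",
              x$id, nchar(x$residues), x$offset,
              x$offset + nchar(x$residues) - 1L))
  invisible(x)
}

seq_len_aa <- function(seq) nchar(seq$residues)

seq_positions <- function(seq) seq$offset + seq_len(nchar(seq$residues)) - 1L

#' Residue at a published position
#'
#' @param seq A [protein_sequence()].
#' @param pos Residue number in the sequence's own numbering.
#' @return Single one-letter residue code.
#' @export
residue_at <- function(seq, pos) {
  i <- pos - seq$offset + 1L
  if (any(i < 1L | i > nchar(seq$residues)))
    stop("position out of range", call. = FALSE)
  substring(seq$residues, i, i)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (single- or multi-record).
#' @param offset Numbering offset applied to every record (recycled).
#' @return List of [protein_sequence()] objects.
#' @export
read_fasta <- function(path, offset = 1L) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path, call. = FALSE)
  offset <- rep_len(as.integer(offset), length(ss))
  out <- lapply(seq_along(ss), function(i) {
    protein_sequence(names(ss)[i], as.character(ss[[i]]), offset[i])
  })
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs A [protein_sequence()] or list of them.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  ss <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(ss) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Default inter-ligand spacing for the RING consensus: allowed counts of
# residues strictly between consecutive ligands.  Gap 4 extends to 4 residues
# so C4C4 domains of the SPE-42 family validate.
DEFAULT_GAP_RANGES <- rbind(
  c(2L, 2L), c(9L, 39L), c(1L, 3L), c(2L, 4L),
  c(2L, 2L), c(4L, 48L), c(2L, 2L)
)

#' Spacing model for RING-finger zinc ligands
#'
#' Defines, for an 8-ligand RING motif, which residues may occupy each ligand
#' slot and how many residues are allowed strictly between consecutive
#' ligands.  The default is the all-cysteine (C4C4) pattern with the classic
#' RING consensus spacing; `mode = "c3hc4"` additionally allows histidine at
#' slot 4, and `allow_aspartate` admits aspartate at every slot.
#'
#' @param gap_ranges Integer matrix with `ligand_count - 1` rows and columns
#'   `min`, `max`; defaults to the RING consensus ranges.
#' @param mode `"c4c4"` (all cysteine) or `"c3hc4"` (histidine allowed at
#'   slot 4).
#' @param allow_aspartate Also allow D at every slot.
#' @return An object of class `spacing_model`.
#' @export
spacing_model <- function(gap_ranges = DEFAULT_GAP_RANGES,
                          mode = c("c4c4", "c3hc4"),
                          allow_aspartate = FALSE) {
  mode <- match.arg(mode)
  gap_ranges <- matrix(as.integer(gap_ranges), ncol = 2L,
                       dimnames = list(NULL, c("min", "max")))
  if (any(is.na(gap_ranges)) || any(gap_ranges[, 1] < 0L))
    stop("gap minima must be non-negative integers", call. = FALSE)
  if (any(gap_ranges[, 1] > gap_ranges[, 2]))
    stop("impossible gap range: min > max", call. = FALSE)
  k <- nrow(gap_ranges) + 1L
  slots <- rep(list("C"), k)
  if (mode == "c3hc4" && k >= 4L) slots[[4L]] <- c("C", "H")
  if (allow_aspartate) slots <- lapply(slots, function(s) unique(c(s, "D")))
  structure(list(ligand_count = k, gap_ranges = gap_ranges,
                 slot_residues = slots, mode = mode),
            class = "spacing_model")
}

cross_brace_partition <- function(positions) {
  if (length(positions) != 8L) return(NULL)
  list(zn1 = positions[c(1L, 2L, 5L, 6L)], zn2 = positions[c(3L, 4L, 7L, 8L)])
}

new_ligand_assignment <- function(positions, all_candidates) {
  structure(list(
    positions = as.integer(positions),
    zinc_partition = cross_brace_partition(as.integer(positions)),
    excluded_candidates = setdiff(as.integer(all_candidates),
                                  as.integer(positions))
  ), class = "ligand_assignment")
}

#' @export
print.ligand_assignment <- function(x, ...) {
  cat("<ligand_assignment>\n")
  cat("  positions:", paste(x$positions, collapse = ", "), "\n")
  cat("  gaps     :", paste(diff(x$positions) - 1L, collapse = ", "), "\n")
  if (!is.null(x$zinc_partition)) {
    cat("  Zn-1     :", paste(x$zinc_partition$zn1, collapse = ", "), "\n")
    cat("  Zn-2     :", paste(x$zinc_partition$zn2, collapse = ", "), "\n")
  }
  if (length(x$excluded_candidates))
    cat("  excluded :", paste(x$excluded_candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Scan a sequence for RING-finger zinc-ligand assignments
#'
#' Enumerates every assignment of candidate residues to the ligand slots of a
#' [spacing_model()] that satisfies all slot-composition and inter-ligand gap
#' constraints.  The search is complete (no valid assignment is missed) and
#' deterministic: results are ordered by first-ligand position, then
#' lexicographically over the remaining positions.  The two zinc ions of a
#' RING domain are partitioned over the 8 ligands in the canonical cross-brace
#' arrangement (ligands 1,2,5,6 to Zn-1 and 3,4,7,8 to Zn-2).
#'
#' @param seq A [protein_sequence()].
#' @param model A [spacing_model()].
#' @return List of `ligand_assignment` objects, possibly empty.  Each carries
#'   `positions` (in the input numbering), `zinc_partition` and
#'   `excluded_candidates` (candidate residues not used by that assignment).
#' @examples
#' s <- gen_ring_sequence(simulation_config(seed = 1))
#' scan_ring_ligands(s$sequence)
#' @export
scan_ring_ligands <- function(seq, model = spacing_model()) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(model, "spacing_model"))
  letters <- strsplit(seq$residues, "")[[1]]
  pos <- seq_positions(seq)
  slot_cand <- lapply(model$slot_residues, function(s) pos[letters %in% s])
  all_cand <- sort(unique(unlist(slot_cand)))
  k <- model$ligand_count
  out <- list()
  recurse <- function(chosen, slot) {
    cand <- slot_cand[[slot]]
    if (slot > 1L) {
      gap <- cand - chosen[slot - 1L] - 1L
      cand <- cand[gap >= model$gap_ranges[slot - 1L, 1L] &
                   gap <= model$gap_ranges[slot - 1L, 2L]]
    }
    for (p in cand) {
      if (slot == k) out[[length(out) + 1L]] <<- c(chosen, p)
      else recurse(c(chosen, p), slot + 1L)
    }
  }
  recurse(integer(0), 1L)
  lapply(out, new_ligand_assignment, all_candidates = all_cand)
}

#' Re-check an assignment against a spacing model
#'
#' Validator independent of the scanner's search: checks strictly increasing
#' positions, slot residue composition, and every inter-ligand gap.
#'
#' @param assignment A `ligand_assignment` or integer vector of positions.
#' @param seq The [protein_sequence()] scanned.
#' @param model The [spacing_model()].
#' @return `TRUE` or `FALSE`.
#' @export
validate_assignment <- function(assignment, seq, model = spacing_model()) {
  p <- if (inherits(assignment, "ligand_assignment")) assignment$positions
       else as.integer(assignment)
  if (length(p) != model$ligand_count) return(FALSE)
  if (any(diff(p) <= 0L)) return(FALSE)
  if (any(p < seq$offset | p >= seq$offset + nchar(seq$residues)))
    return(FALSE)
  res <- vapply(p, function(q) residue_at(seq, q), "")
  ok_slot <- mapply(function(r, allowed) r %in% allowed,
                    res, model$slot_residues)
  if (!all(ok_slot)) return(FALSE)
  gaps <- diff(p) - 1L
  all(gaps >= model$gap_ranges[, 1L] & gaps <= model$gap_ranges[, 2L])
}

#' Select the unique ligand assignment from a scan
#'
#' @param assignments List returned by [scan_ring_ligands()].
#' @return The single assignment when exactly one exists.  Signals a
#'   condition of class `ringscape_no_motif` on an empty list and
#'   `ringscape_ambiguous` (carrying all candidates in field `candidates`)
#'   when several remain.
#' @export
assign_unique <- function(assignments) {
  n <- length(assignments)
  if (n == 0L)
    stop(structure(class = c("ringscape_no_motif", "error", "condition"),
                   list(message = "no RING motif found", call = NULL)))
  if (n > 1L)
    stop(structure(class = c("ringscape_ambiguous", "error", "condition"),
                   list(message = sprintf("ambiguous: %d valid assignments", n),
                        call = NULL, candidates = assignments)))
  assignments[[1L]]
}

blosum_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

divergence_report <- function(identity, similarity, window = NULL) {
  structure(list(percent_identity = identity, percent_similarity = similarity,
                 window = window),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("<divergence_report> identity %.1f%%, similarity %.1f%%%s\n",
              x$percent_identity, x$percent_similarity,
              if (is.null(x$window)) "" else
                sprintf(" (window of %d columns)", length(x$window))))
  invisible(x)
}

# identity = identical columns / all alignment columns (gap columns included
# in the denominator); similarity additionally counts residue pairs with a
# positive substitution score.
divergence_from_columns <- function(ca, cb, submat, columns = NULL) {
  if (is.null(columns)) columns <- seq_along(ca)
  a <- ca[columns]; b <- cb[columns]
  ncols <- length(columns)
  both <- a != "-" & b != "-"
  ident <- both & a == b
  s <- rep(FALSE, ncols)
  if (any(both))
    s[both] <- submat[cbind(a[both], b[both])] > 0
  similar <- ident | s
  divergence_report(100 * sum(ident) / ncols, 100 * sum(similar) / ncols,
                    window = if (length(columns) < length(ca)) columns)
}

#' Global pairwise alignment with divergence statistics
#'
#' Needleman-Wunsch global alignment with affine gap penalties (via
#' `Biostrings::pairwiseAlignment`), followed by column-wise percent identity
#' and similarity.  Identity is the fraction of alignment columns (gap
#' columns included in the denominator) with identical residues; similarity
#' additionally counts residue pairs whose substitution score is positive.
#'
#' @param a,b [protein_sequence()] objects (or plain strings).
#' @param substitution Substitution matrix name in Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return An object of class `pairwise_alignment` with fields `aligned_a`,
#'   `aligned_b`, `score`, and `report` (a `divergence_report`).
#' @export
pairwise_global_align <- function(a, b, substitution = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5) {
  if (is.character(a)) a <- protein_sequence("a", a)
  if (is.character(b)) b <- protein_sequence("b", b)
  stopifnot(inherits(a, "protein_sequence"), inherits(b, "protein_sequence"))
  submat <- if (is.character(substitution)) blosum_matrix(substitution)
            else substitution
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aa <- as.character(Biostrings::alignedPattern(aln))
  ab <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(aa, "")[[1]]; cb <- strsplit(ab, "")[[1]]
  structure(list(a = a, b = b, aligned_a = aa, aligned_b = ab,
                 score = Biostrings::score(aln),
                 report = divergence_from_columns(ca, cb, submat),
                 submat = submat),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s, score %.1f\n",
              x$a$id, x$b$id, x$score))
  print(x$report)
  invisible(x)
}

#' Divergence restricted to the C-terminal tails
#'
#' Recomputes percent identity and similarity over the alignment columns that
#' contain any of the last `tail_a` residues of the first sequence or the
#' last `tail_b` residues of the second — the window used to contrast a
#' divergent C-terminus with the rest of the protein.
#'
#' @param aln A `pairwise_alignment` from [pairwise_global_align()].
#' @param tail_a,tail_b Tail lengths (residues) for the two sequences.
#' @return A `divergence_report` with the window columns recorded.
#' @export
cterminal_divergence <- function(aln, tail_a, tail_b) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  na <- sum(ca != "-"); nb <- sum(cb != "-")
  if (tail_a > na || tail_b > nb)
    stop("tail longer than sequence", call. = FALSE)
  ia <- cumsum(ca != "-")          # residue index of a at/before each column
  ib <- cumsum(cb != "-")
  in_a <- ca != "-" & ia > na - tail_a
  in_b <- cb != "-" & ib > nb - tail_b
  cols <- which(in_a | in_b)
  divergence_from_columns(ca, cb, aln$submat, columns = cols)
}

#' Serialize scan results to JSON
#'
#' @param assignments List from [scan_ring_ligands()].
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @export
scan_to_json <- function(assignments, path = NULL) {
  payload <- lapply(assignments, function(a) {
    list(positions = a$positions,
         gaps = diff(a$positions) - 1L,
         zinc_partition = a$zinc_partition,
         excluded_candidates = a$excluded_candidates)
  })
  js <- jsonlite::toJSON(list(n_assignments = length(assignments),
                              assignments = payload),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
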