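# Seeded generators for everything the pipeline consumes: motif-bearing
# sequences, toy two-zinc-site structures with a partner chain, and
# brood-count tables with planted rescue fractions.  All generators are pure
# functions of a SimulationConfig: same seed, byte-identical output.

#' Simulation configuration
#'
#' Bundles the parameters of the three generators.  Defaults emulate the
#' assay and domain scale of the RING-finger rescue study: an ~60-residue
#' C-terminal domain with the 8-cysteine C4C4 spacing, idealized tetrahedral
#' zinc sites at the canonical 2.3 A Zn-S bond length, and brood tables with
#' 3 independently derived lines per genotype and ~10 worms per line around a
#' wild-type transgene grand mean of 110 progeny.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param sequence Sequence-generator parameters: `length`, `offset`,
#'   `motif_start` (position of the first ligand), `gap_vector` (7 inter-
#'   ligand gaps, default the SPE-42 spacing `c(2, 15, 2, 4, 2, 6, 2)`),
#'   `background` (residue alphabet for non-ligand positions; cysteine-free).
#' @param structure Structure-generator parameters: `zn_s_dist` (A),
#'   `ca_dist` (A, CA shell radius), `site_sep` (A between the two zincs),
#'   `jitter_sd` (A, Gaussian coordinate noise), `cutoff` (A, contact
#'   definition used for the planted ground truth).
#' @param broods Brood-generator parameters: `wt_mean`, `nb_size` (negative
#'   binomial dispersion), `line_sdlog` (SD of the log-normal line random
#'   effect), `lines_per_genotype`, `worms_per_line`, `fractions` (named
#'   genotype-to-fraction map), `zi_prob` (optional zero inflation).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              sequence = list(),
                              structure = list(),
                              broods = list()) {
  seq_def <- list(length = 60L, offset = 670L, motif_start = 681L,
                  gap_vector = c(2L, 15L, 2L, 4L, 2L, 6L, 2L),
                  background = setdiff(strsplit("ADEFGHIKLMNPQRSTVWY",
                                                "")[[1]], "C"))
  str_def <- list(zn_s_dist = 2.3, ca_dist = 4.5, site_sep = 20,
                  jitter_sd = 0.05, cutoff = 5.0)
  br_def <- list(wt_mean = 110, nb_size = 5, line_sdlog = 0.2,
                 lines_per_genotype = 3L, worms_per_line = 10L,
                 fractions = c("wild type" = 1, "mutant" = 0.5),
                 zi_prob = 0)
  merge <- function(def, user) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown parameters: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    def[names(user)] <- user
    def
  }
  cfg <- list(seed = as.integer(seed),
              sequence = merge(seq_def, sequence),
              structure = merge(str_def, structure),
              broods = merge(br_def, broods))
  if (cfg$structure$jitter_sd < 0 || cfg$broods$line_sdlog < 0)
    stop("negative dispersion parameter", call. = FALSE)
  if (any(cfg$broods$fractions < 0))
    stop("negative rescue fraction", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a motif-bearing protein sequence with ground truth
#'
#' Plants an 8-ligand cysteine motif with the configured inter-ligand gap
#' vector into a cysteine-free random background, so the scanner's recovery
#' of the planted assignment is a closed loop.
#'
#' @param config A [simulation_config()].
#' @return List with `sequence` (a [protein_sequence()]), `positions` (the
#'   planted ligand positions) and `assignment` (the planted
#'   `ligand_assignment`).
#' @export
gen_ring_sequence <- function(config = simulation_config()) {
  p <- config$sequence
  set.seed(config$seed)
  span <- sum(p$gap_vector) + 8L
  start_i <- p$motif_start - p$offset + 1L
  if (start_i < 1L || start_i + span - 1L > p$length)
    stop("sequence too short for the planted gap vector", call. = FALSE)
  letters <- sample(p$background, p$length, replace = TRUE)
  pos_i <- start_i + cumsum(c(0L, p$gap_vector + 1L))
  letters[pos_i] <- "C"
  seq <- protein_sequence("synthetic_ring", paste(letters, collapse = ""),
                          offset = p$offset)
  positions <- p$offset + pos_i - 1L
  list(sequence = seq, positions = positions,
       assignment = new_ligand_assignment(positions, positions))
}

tetrahedron_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

#' Generate a toy two-site zinc structure with a partner chain
#'
#' Builds two idealized tetrahedral zinc sites (four cysteine pseudo-residues
#' each, SG at the configured Zn-S distance and CA on a wider shell along the
#' same direction), with the ligand residues of chain A numbered 1..8 in the
#' cross-brace arrangement (residues 1,2,5,6 at site 1; 3,4,7,8 at site 2).
#' A partner chain B carries one pseudo-atom adjacent to site 1 — so the
#' planted interface is exactly the site-1 residues — and one far-away
#' pseudo-atom.  Gaussian jitter is applied last; generation refuses when the
#' jitter could blur the ground truth (any pre-jitter residue-to-partner
#' minimum distance inside `cutoff +/- 2 * jitter_sd`).
#'
#' @param config A [simulation_config()].
#' @return List with `model` (a [structure_model()]), `contacts` (planted
#'   interface residues of chain A), and `ligand_resnos` (1..8, for
#'   [zinc_geometry_check()]).
#' @export
gen_ring_structure <- function(config = simulation_config()) {
  p <- config$structure
  set.seed(config$seed)
  dirs <- tetrahedron_dirs()
  zn <- rbind(c(0, 0, 0), c(p$site_sep, 0, 0))
  # residue -> (site, tetrahedron vertex): cross-brace over the two zincs
  slot <- data.frame(resno = 1:8,
                     site = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L),
                     vertex = c(1L, 2L, 1L, 2L, 3L, 4L, 3L, 4L))
  rows <- do.call(rbind, lapply(seq_len(nrow(slot)), function(i) {
    z <- zn[slot$site[i], ]; d <- dirs[slot$vertex[i], ]
    rbind(
      data.frame(chain = "A", resno = slot$resno[i], resname = "CYS",
                 atom = "CA", x = z[1] + p$ca_dist * d[1],
                 y = z[2] + p$ca_dist * d[2], z = z[3] + p$ca_dist * d[3]),
      data.frame(chain = "A", resno = slot$resno[i], resname = "CYS",
                 atom = "SG", x = z[1] + p$zn_s_dist * d[1],
                 y = z[2] + p$zn_s_dist * d[2], z = z[3] + p$zn_s_dist * d[3]))
  }))
  partner <- rbind(
    data.frame(chain = "B", resno = 1L, resname = "GLY", atom = "CA",
               x = 0, y = 0, z = 0.3),
    data.frame(chain = "B", resno = 2L, resname = "GLY", atom = "CA",
               x = 2 * p$site_sep, y = 0, z = 0))
  atoms <- rbind(rows, partner)
  atoms <- atoms[order(match(atoms$chain, c("A", "B")), atoms$resno,
                       atoms$atom), ]
  # ground truth before jitter: residue-to-partner minimum distances
  ai <- atoms$chain == "A"
  d2 <- pairwise_sq_dists(as.matrix(atoms[ai, c("x", "y", "z")]),
                          as.matrix(atoms[!ai, c("x", "y", "z")]))
  mind <- sqrt(tapply(apply(d2, 1L, min), atoms$resno[ai], min))
  band <- abs(mind - p$cutoff) <= 2 * p$jitter_sd
  if (any(band))
    stop("jitter too large: planted contacts are ambiguous at this cutoff",
         call. = FALSE)
  contacts <- as.integer(names(mind)[mind <= p$cutoff])
  if (p$jitter_sd > 0) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    atoms[, c("x", "y", "z")] <- xyz +
      matrix(stats::rnorm(length(xyz), 0, p$jitter_sd), ncol = 3L)
  }
  metals <- data.frame(elem = c("ZN", "ZN"), x = zn[, 1], y = zn[, 2],
                       z = zn[, 3])
  rownames(atoms) <- NULL
  list(model = structure_model(atoms, metals),
       contacts = data.frame(chain = "A", resno = sort(contacts)),
       ligand_resnos = 1:8)
}

#' Generate brood-count tables with planted rescue fractions
#'
#' Per-worm counts are negative binomial around `wt_mean * fraction *
#' line_effect`, with a log-normal per-line random effect capturing the large
#' array-to-array spread seen in transgenic rescue tables; optional zero
#' inflation mimics fully sterile worms.  `nb_size = Inf` gives the Poisson
#' limit.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (long `data.frame`: genotype, transgene_id,
#'   worm_id, progeny_total), `lines` (list of [rescue_line()] objects) and
#'   `truth` (planted fractions and line effects).
#' @export
gen_broods <- function(config = simulation_config()) {
  p <- config$broods
  if (p$wt_mean <= 0) stop("wild-type mean must be positive", call. = FALSE)
  set.seed(config$seed)
  rows <- list(); lines <- list(); effects <- list()
  for (g in names(p$fractions)) {
    f <- p$fractions[[g]]
    for (l in seq_len(p$lines_per_genotype)) {
      eff <- stats::rlnorm(1L, 0, p$line_sdlog)
      mu <- p$wt_mean * f * eff
      counts <- if (is.infinite(p$nb_size)) stats::rpois(p$worms_per_line, mu)
                else stats::rnbinom(p$worms_per_line, mu = mu, size = p$nb_size)
      if (p$zi_prob > 0)
        counts[stats::runif(p$worms_per_line) < p$zi_prob] <- 0L
      id <- sprintf("%s_line%d", gsub("\\s+", "_", g), l)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, transgene_id = id,
        worm_id = seq_len(p$worms_per_line), progeny_total = counts)
      lines[[length(lines) + 1L]] <- rescue_line(id, g, counts = counts)
      effects[[id]] <- eff
    }
  }
  list(table = do.call(rbind, rows), lines = lines,
       truth = list(fractions = p$fractions,
                    line_effects = unlist(effects)))
}
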