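# Synthetic multi-strain pangenomes with planted gene families.
#
# Each species draws its own codon-usage distribution from a Dirichlet over
# the 61 sense codons (biased toward a target GC content); each gene family
# has an ancestral codon sequence drawn i.i.d. from that usage, and each
# strain carries a mutated copy (codon-level resampling at the configured
# rate, which keeps the reading frame and can never introduce an in-frame
# stop). Every other module is testable against the emitted truth table.

#' Configuration of a synthetic pangenome
#'
#' Defaults describe a modest multi-strain bacterial species panel: four
#' sequenced strains per species, 400 conserved gene families of 100--400
#' codons, strongly species-specific codon usage (Dirichlet total
#' concentration 5 over 61 codons), and 2\% per-codon within-family
#' divergence (about 1.4\% nucleotide divergence, typical of conspecific
#' strains' core genes).
#'
#' @param n_species Number of species.
#' @param strains_per_species Genomes per species.
#' @param families_per_species Conserved gene families per species.
#' @param family_length_range Min/max ancestral length in codons (>= 20).
#' @param codon_usage_concentration Total Dirichlet concentration; smaller
#'   values give spikier, more biased codon usage.
#' @param within_family_divergence Per-codon resampling probability per
#'   strain, in [0, 0.75).
#' @param gc_target Target GC fraction biasing the Dirichlet base measure.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_species = 1L, strains_per_species = 4L,
                              families_per_species = 400L,
                              family_length_range = c(100L, 400L),
                              codon_usage_concentration = 5,
                              within_family_divergence = 0.02,
                              gc_target = 0.5, seed = 1L) {
  stopifnot(n_species >= 1L, strains_per_species >= 1L,
            families_per_species >= 1L)
  if (any(family_length_range < 20L))
    stop("family lengths must be at least 20 codons")
  if (within_family_divergence < 0 || within_family_divergence >= 0.75)
    stop("within_family_divergence must be in [0, 0.75)")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  structure(
    list(n_species = as.integer(n_species),
         strains_per_species = as.integer(strains_per_species),
         families_per_species = as.integer(families_per_species),
         family_length_range = as.integer(family_length_range),
         codon_usage_concentration = codon_usage_concentration,
         within_family_divergence = within_family_divergence,
         gc_target = gc_target, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

codon_gc_base_measure <- function(gc_target) {
  base_w <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
              G = gc_target / 2, T = (1 - gc_target) / 2)
  w <- vapply(SENSE_CODONS, function(cdn) {
    prod(base_w[strsplit(cdn, "")[[1L]]])
  }, numeric(1))
  w / sum(w)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic multi-strain pangenome
#'
#' @param config A [simulation_config()].
#' @return List with \code{orfs} (ORF table: \code{species_id},
#'   \code{genome_id}, \code{orf_id}, \code{seq} — full ORFs with ATG start
#'   and TAA stop), \code{truth} (adds \code{family_id} per ORF),
#'   \code{usage} (per-species codon usage over [SENSE_CODONS]), and
#'   \code{config}.
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    q0 <- codon_gc_base_measure(config$gc_target)
    usage <- list()
    rows <- list()
    for (sp in seq_len(config$n_species)) {
      species_id <- sprintf("sp%02d", sp)
      u <- rdirichlet1(config$codon_usage_concentration * q0)
      usage[[species_id]] <- stats::setNames(u, SENSE_CODONS)
      lens <- sample(seq(config$family_length_range[1L],
                         config$family_length_range[2L]),
                     config$families_per_species, replace = TRUE)
      for (fam in seq_len(config$families_per_species)) {
        anc <- sample.int(61L, lens[fam], replace = TRUE, prob = u)
        for (st in seq_len(config$strains_per_species)) {
          mut <- anc
          hit <- stats::runif(length(anc)) < config$within_family_divergence
          if (any(hit))
            mut[hit] <- sample.int(61L, sum(hit), replace = TRUE, prob = u)
          rows[[length(rows) + 1L]] <- data.frame(
            species_id = species_id,
            genome_id = sprintf("%s.g%02d", species_id, st),
            orf_id = sprintf("%s.g%02d.f%04d", species_id, st, fam),
            family_id = sprintf("%s.f%04d", species_id, fam),
            seq = paste0("ATG", paste(SENSE_CODONS[mut], collapse = ""), "TAA"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    truth <- do.call(rbind, rows)
    list(orfs = truth[, c("species_id", "genome_id", "orf_id", "seq")],
         truth = truth[, c("species_id", "genome_id", "orf_id", "family_id")],
         usage = usage, config = config)
  })
}

#' Toy all-vs-all bitscores from shared k-mers
#'
#' A self-contained stand-in for an all-against-all reciprocal alignment
#' search: the score s(i;j) is the number of distinct k-mers the two
#' sequences share (k = 8 by default), and s(i;i) is the sequence's own
#' distinct k-mer count. Scores are symmetric by construction and
#' self-scores are strictly positive, which is all [bitscore_distances()]
#' requires. Both directions of every overlapping pair are emitted, plus
#' self rows; unscored pairs are treated as score 0 downstream.
#'
#' @param orfs ORF table with \code{orf_id} and \code{seq}.
#' @param k k-mer length (default 8).
#' @return Bitscore table: \code{query}, \code{subject}, \code{score}.
#' @export
generate_bitscores <- function(orfs, k = 8L) {
  if (nrow(orfs) == 0L || any(nchar(orfs$seq) < k))
    stop("all sequences must be non-empty and at least k long")
  kmer_sets <- lapply(orfs$seq, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  dict <- unique(unlist(kmer_sets, use.names = FALSE))
  j_idx <- lapply(kmer_sets, match, table = dict)
  M <- Matrix::sparseMatrix(
    i = rep.int(seq_along(j_idx), lengths(j_idx)),
    j = unlist(j_idx, use.names = FALSE),
    x = 1,
    dims = c(nrow(orfs), length(dict))
  )
  S <- Matrix::tcrossprod(M)
  Str <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  qi <- Str@i + 1L
  sj <- Str@j + 1L
  keep <- Str@x > 0
  data.frame(
    query = orfs$orf_id[qi[keep]],
    subject = orfs$orf_id[sj[keep]],
    score = Str@x[keep],
    stringsAsFactors = FALSE
  )
}

#' Build one species' Positive/Negative training set
#'
#' Runs the full dataset construction on one species' ORFs: toy bitscores,
#' distances, similarity graph at threshold t, HCO extraction, medoid
#' Positives (capped), and the 5 out-of-frame Negatives per Positive.
#'
#' @param orfs ORF table of a single species (full ORFs including start and
#'   stop codons).
#' @param t Distance threshold (default 0.3).
#' @param cap Positive cap per species (default 400).
#' @param seed Seed for the Positive subsample.
#' @param kmer k-mer length of the toy scorer.
#' @param bitscores Optional precomputed bitscore table (e.g. from a real
#'   aligner) — when supplied the toy scorer is skipped.
#' @return List: \code{positives}, \code{negatives}, \code{dataset}
#'   (row-bound labeled ORFs), \code{hcos}, \code{graph}.
#' @export
build_species_dataset <- function(orfs, t = 0.3, cap = 400L, seed = NULL,
                                  kmer = 8L, bitscores = NULL) {
  stopifnot(length(unique(orfs$species_id)) == 1L)
  if (is.null(bitscores)) bitscores <- generate_bitscores(orfs, k = kmer)
  distances <- bitscore_distances(bitscores)
  genomes <- stats::setNames(orfs$genome_id, orfs$orf_id)
  graph <- build_graph(distances, genomes, t = t)
  hcos <- extract_hcos(graph, unique(orfs$genome_id))
  positives <- sample_positives(hcos, orfs, cap = cap, seed = seed)
  negatives <- make_negatives_set(positives)
  list(positives = positives, negatives = negatives,
       dataset = rbind(positives, negatives), hcos = hcos, graph = graph)
}

#' Labeled dataset straight from the generator's truth table
#'
#' Shortcut for classifier studies that do not exercise the clustering
#' stage: one Positive per planted family (the first strain's copy),
#' optionally capped, with the usual out-of-frame Negatives.
#'
#' @param pangenome Output of [generate_pangenome()].
#' @param species_id Species to extract (default: first).
#' @param cap Optional Positive cap.
#' @param seed Seed for the cap subsample.
#' @return List: \code{positives}, \code{negatives}, \code{dataset}.
#' @export
truth_dataset <- function(pangenome, species_id = NULL, cap = NULL,
                          seed = NULL) {
  truth <- pangenome$truth
  if (is.null(species_id)) species_id <- truth$species_id[1L]
  sel <- truth$species_id == species_id
  truth <- truth[sel, , drop = FALSE]
  orfs <- pangenome$orfs[sel, , drop = FALSE]
  first <- !duplicated(truth$family_id)
  pos_raw <- orfs[first, , drop = FALSE]
  if (!is.null(cap) && nrow(pos_raw) > cap) {
    idx <- with_seed(seed, sample(nrow(pos_raw), cap))
    pos_raw <- pos_raw[idx, , drop = FALSE]
  }
  positives <- data.frame(
    species_id = pos_raw$species_id, genome_id = pos_raw$genome_id,
    orf_id = pos_raw$orf_id,
    seq = vapply(pos_raw$seq, strip_start_and_stops, character(1),
                 USE.NAMES = FALSE),
    raw = pos_raw$seq, label = 1L, stringsAsFactors = FALSE
  )
  negatives <- make_negatives_set(positives)
  list(positives = positives, negatives = negatives,
       dataset = rbind(positives, negatives))
}

#' Null dataset: both classes from one codon-usage distribution
#'
#' Draws Positives and Negatives i.i.d. from the same codon usage (1:5
#' class ratio by default), so no signal separates the classes and a
#' classifier can do no better than the majority rate in expectation.
#'
#' @param n_positives Number of Positives; Negatives are
#'   \code{ratio} times as many.
#' @param ratio Negatives per Positive (default 5).
#' @param length_range Sequence length range in codons.
#' @param codon_usage_concentration,gc_target As in [simulation_config()].
#' @param seed Integer seed.
#' @return Labeled ORF table (stripped sequences, labels +1 / -1).
#' @export
null_dataset <- function(n_positives = 60L, ratio = 5L,
                         length_range = c(100L, 200L),
                         codon_usage_concentration = 5, gc_target = 0.5,
                         seed = 1L) {
  with_seed(seed, {
    u <- rdirichlet1(codon_usage_concentration * codon_gc_base_measure(gc_target))
    n <- n_positives * (1L + ratio)
    lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(SENSE_CODONS[sample.int(61L, L, replace = TRUE, prob = u)],
            collapse = "")
    }, character(1))
    data.frame(
      species_id = "null", genome_id = "null.g01",
      orf_id = sprintf("null.orf%05d", seq_len(n)),
      seq = seqs,
      label = rep(c(1L, -1L), c(n_positives, n - n_positives)),
      stringsAsFactors = FALSE
    )
  })
}
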