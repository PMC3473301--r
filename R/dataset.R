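#' Pairwise distance between two ORFs from alignment bitscores
#'
#' With s(i;j) the bitscore of the alignment between query i and subject j,
#' \deqn{d(i,j) = 1 - \frac{s(i;j) + s(j;i)}{s(i;i) + s(j;j)}}
#' which lies in [0, 1]: 0 for identical sequences, 1 when neither aligns to
#' the other. A missing reciprocal hit is treated as bitscore 0.
#'
#' @param s_ij,s_ji Cross bitscores (query i vs subject j and vice versa).
#' @param s_ii,s_jj Self-alignment bitscores; their sum must be positive.
#' @return Distance in [0, 1] (clamped). Vectorized.
#' @examples
#' pairwise_distance(30, 34, 80, 48)  # 0.5
#' @export
pairwise_distance <- function(s_ij, s_ji, s_ii, s_jj) {
  if (any(c(s_ij, s_ji, s_ii, s_jj) < 0)) stop("bitscores must be >= 0")
  if (any(s_ii + s_jj <= 0)) stop("self-score sum must be positive")
  pmin(1, pmax(0, 1 - (s_ij + s_ji) / (s_ii + s_jj)))
}

#' Distances for all scored ORF pairs in a bitscore table
#'
#' @param bitscores Data frame with columns \code{query}, \code{subject},
#'   \code{score} (e.g. from [read_bitscores()] or [generate_bitscores()]).
#'   Self scores \code{s(i;i)} must be present for every id.
#' @return Data frame with columns \code{orf_i}, \code{orf_j} (unordered
#'   pairs, i < j lexicographically) and \code{d}.
#' @export
bitscore_distances <- function(bitscores) {
  stopifnot(all(c("query", "subject", "score") %in% names(bitscores)))
  self <- bitscores$score[bitscores$query == bitscores$subject]
  names(self) <- bitscores$query[bitscores$query == bitscores$subject]
  ids <- unique(c(bitscores$query, bitscores$subject))
  missing_self <- setdiff(ids, names(self))
  if (length(missing_self) > 0L)
    stop("missing self-scores for: ", paste(utils::head(missing_self, 5L),
                                            collapse = ", "))
  if (any(self <= 0)) stop("self-scores must be strictly positive")
  cross <- bitscores[bitscores$query != bitscores$subject, , drop = FALSE]
  if (nrow(cross) == 0L)
    return(data.frame(orf_i = character(0), orf_j = character(0),
                      d = numeric(0), stringsAsFactors = FALSE))
  a <- pmin(cross$query, cross$subject)
  b <- pmax(cross$query, cross$subject)
  key <- paste(a, b, sep = "\r")
  # sum the two directed scores per unordered pair; a missing direction adds 0
  ssum <- rowsum(cross$score, key)
  uk <- rownames(ssum)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  orf_i <- vapply(parts, `[`, character(1), 1L)
  orf_j <- vapply(parts, `[`, character(1), 2L)
  data.frame(
    orf_i = orf_i, orf_j = orf_j,
    d = pmin(1, pmax(0, 1 - ssum[, 1L] / (self[orf_i] + self[orf_j]))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build the ORF similarity graph
#'
#' Nodes are ORFs (tagged with their genome); an undirected edge joins two
#' ORFs whose distance d(i,j) is at or below the threshold t. Connected
#' components of this graph are the candidate gene clusters.
#'
#' @param distances Data frame from [bitscore_distances()] (columns
#'   \code{orf_i}, \code{orf_j}, \code{d}).
#' @param genomes Named character vector: genome id per ORF id. Its names
#'   define the node set (ORFs with no similar partner become isolated
#'   nodes).
#' @param t Distance threshold in [0, 1]; default 0.3 keeps pairs that are
#'   roughly 70\% similar or more.
#' @return An object of class \code{similarity_graph}: list with the igraph
#'   \code{graph} (edge attribute \code{weight} = d), \code{threshold}, and
#'   the full \code{distances} table (kept for medoid computation).
#' @export
build_graph <- function(distances, genomes, t = 0.3) {
  if (t < 0 || t > 1) stop("t must be in [0, 1]")
  if (is.null(names(genomes))) stop("genomes must be named by ORF id")
  keep <- distances$d <= t
  edges <- distances[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$orf_i, to = edges$orf_j, weight = edges$d),
    directed = FALSE,
    vertices = data.frame(name = names(genomes), genome = unname(genomes))
  )
  structure(
    list(graph = g, threshold = t, distances = distances),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d ORFs, %d edges at t = %g\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Extract highly conserved ORF (HCO) clusters
#'
#' A connected component of the similarity graph is a highly conserved ORF
#' when it contains at least one member from every genome of the species.
#' Each HCO is represented by its medoid: the member with the smallest sum
#' of distances to all other members (all pairwise distances are used, not
#' only edges at or below the threshold; an unscored pair counts as
#' distance 1). Ties go to the lexicographically first id.
#'
#' @param graph A \code{similarity_graph} from [build_graph()].
#' @param genome_set Character vector of all genome ids of the species.
#' @return Data frame with one row per HCO: \code{cluster_id},
#'   \code{medoid_id}, \code{n_members}, and list-column \code{members}.
#' @export
extract_hcos <- function(graph, genome_set) {
  stopifnot(inherits(graph, "similarity_graph"))
  genome_set <- unique(genome_set)
  if (length(genome_set) == 0L) stop("genome_set must be non-empty")
  g <- graph$graph
  node_genome <- igraph::vertex_attr(g, "genome")
  names(node_genome) <- igraph::vertex_attr(g, "name")
  if (!all(node_genome %in% genome_set))
    stop("graph contains nodes from genomes outside genome_set")
  comp <- igraph::components(g)
  membership <- split(names(node_genome), comp$membership)

  dist_lookup <- graph$distances
  dkey <- paste(pmin(dist_lookup$orf_i, dist_lookup$orf_j),
                pmax(dist_lookup$orf_i, dist_lookup$orf_j), sep = "\r")
  dmap <- dist_lookup$d
  names(dmap) <- dkey

  out <- list()
  cid <- 0L
  for (members in membership) {
    covered <- unique(node_genome[members])
    if (!all(genome_set %in% covered)) next
    members <- sort(members)
    if (length(members) == 1L) {
      medoid <- members  # single-genome species, singleton cluster
    } else {
      pairs <- utils::combn(members, 2L)
      key <- paste(pairs[1L, ], pairs[2L, ], sep = "\r")
      dv <- dmap[key]
      dv[is.na(dv)] <- 1  # pair never scored
      sums <- numeric(length(members))
      names(sums) <- members
      for (e in seq_along(dv)) {
        sums[pairs[1L, e]] <- sums[pairs[1L, e]] + dv[e]
        sums[pairs[2L, e]] <- sums[pairs[2L, e]] + dv[e]
      }
      medoid <- names(sums)[which.min(sums)]
    }
    cid <- cid + 1L
    out[[cid]] <- list(cluster_id = cid, medoid_id = medoid,
                       n_members = length(members), members = members)
  }
  if (length(out) == 0L)
    return(data.frame(cluster_id = integer(0), medoid_id = character(0),
                      n_members = integer(0),
                      members = I(list()), stringsAsFactors = FALSE))
  data.frame(
    cluster_id = vapply(out, `[[`, integer(1), "cluster_id"),
    medoid_id = vapply(out, `[[`, character(1), "medoid_id"),
    n_members = vapply(out, `[[`, integer(1), "n_members"),
    members = I(lapply(out, `[[`, "members")),
    stringsAsFactors = FALSE
  )
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Select Positive training sequences from HCO medoids
#'
#' Takes the medoid of every HCO; if the species has more than \code{cap}
#' HCOs, a uniform random sample of \code{cap} medoids is used. Sequences
#' are preprocessed with [strip_start_and_stops()]; the raw sequence is kept
#' for Negative construction.
#'
#' @param hcos HCO table from [extract_hcos()].
#' @param orfs ORF table (columns \code{species_id}, \code{genome_id},
#'   \code{orf_id}, \code{seq}) holding the medoid sequences.
#' @param cap Maximum number of Positives per species (default 400).
#' @param seed Optional integer seed making the subsample reproducible.
#' @return Labeled ORF table: columns of \code{orfs} plus \code{raw} (the
#'   unstripped sequence) and \code{label} = +1; \code{seq} is stripped.
#' @export
sample_positives <- function(hcos, orfs, cap = 400L, seed = NULL) {
  if (cap <= 0) stop("cap must be positive")
  if (nrow(hcos) == 0L) stop("no HCO clusters to sample Positives from")
  medoids <- hcos$medoid_id
  if (length(medoids) > cap)
    medoids <- with_seed(seed, sample(medoids, cap))
  idx <- match(medoids, orfs$orf_id)
  if (anyNA(idx)) stop("medoid id(s) missing from ORF table")
  pos <- orfs[idx, , drop = FALSE]
  data.frame(
    species_id = pos$species_id, genome_id = pos$genome_id,
    orf_id = pos$orf_id,
    seq = vapply(pos$seq, strip_start_and_stops, character(1),
                 USE.NAMES = FALSE),
    raw = pos$seq, label = 1L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' The five out-of-frame readings of a Positive ORF
#'
#' A coding sequence has five out-of-frame readings: the same strand shifted
#' by +1 and +2 nucleotides, and the three reading frames of the reverse
#' complement. Each reading is trimmed to whole codons and stripped of its
#' first start codon and all in-frame stop codons, exactly like the
#' Positives; the results are labeled -1. A reading left empty by stripping
#' is dropped with a warning (so fewer than 5 Negatives can be returned only
#' for degenerate input).
#'
#' @param raw_sequence The Positive's original nucleotide sequence (before
#'   stripping).
#' @param species_id,genome_id,orf_id Identifiers copied to the Negatives;
#'   \code{orf_id} gets a \code{:fwd1}, \code{:fwd2}, \code{:rc0},
#'   \code{:rc1} or \code{:rc2} suffix.
#' @return Labeled ORF table of up to 5 rows with \code{label} = -1.
#' @export
make_negatives <- function(raw_sequence, species_id = NA_character_,
                           genome_id = NA_character_, orf_id = "orf") {
  check_nucleotides(raw_sequence)
  rc <- reverse_complement(raw_sequence)
  frames <- c(
    fwd1 = substr(raw_sequence, 2L, nchar(raw_sequence)),
    fwd2 = substr(raw_sequence, 3L, nchar(raw_sequence)),
    rc0 = rc,
    rc1 = substr(rc, 2L, nchar(rc)),
    rc2 = substr(rc, 3L, nchar(rc))
  )
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    stripped <- tryCatch(strip_start_and_stops(frames[[f]]),
                         error = function(e) NULL)
    if (is.null(stripped)) {
      warning(sprintf("frame %s of %s degenerate after stripping; dropped",
                      names(frames)[f], orf_id))
      next
    }
    out[[f]] <- data.frame(
      species_id = species_id, genome_id = genome_id,
      orf_id = paste0(orf_id, ":", names(frames)[f]),
      seq = stripped, raw = frames[[f]], label = -1L,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Negatives for every Positive in a labeled ORF table
#'
#' @param positives Labeled ORF table from [sample_positives()] (needs the
#'   \code{raw} column).
#' @return Labeled ORF table of (up to) 5 rows per Positive, label -1.
#' @export
make_negatives_set <- function(positives) {
  stopifnot("raw" %in% names(positives))
  neg <- mapply(make_negatives,
                positives$raw, positives$species_id,
                positives$genome_id, positives$orf_id,
                SIMPLIFY = FALSE)
  do.call(rbind, c(neg, list(make.row.names = FALSE)))
}

#' Stratified fold assignment for cross-validation
#'
#' Randomly partitions the data into near-equal folds, separately within
#' Positives and Negatives so that every fold sees both classes in their
#' overall proportion.
#'
#' @param labels Vector of class labels (+1 / -1).
#' @param folds Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids (1..folds), one per item.
#' @export
split_folds <- function(labels, folds = 10L, seed = NULL) {
  if (folds < 2L) stop("folds must be >= 2")
  tab <- table(labels)
  if (any(tab < folds))
    stop(sprintf("class %s has %d item(s), fewer than %d folds",
                 names(tab)[which.min(tab)], min(tab), folds))
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cls in names(tab)) {
      idx <- which(as.character(labels) == cls)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

# ---- file formats -----------------------------------------------------------

#' Read ORF sequences from FASTA
#'
#' Record ids encode \code{species|genome|orf} and optionally \code{|label}
#' (+1/-1). Wrapped lines and CRLF endings are handled by the Biostrings
#' parser.
#'
#' @param path FASTA file path (or vector of paths).
#' @return ORF table: \code{species_id}, \code{genome_id}, \code{orf_id},
#'   \code{seq}, and \code{label} where present (NA otherwise).
#' @export
read_orf_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(ids, "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("FASTA ids must encode species|genome|orf[|label]")
  data.frame(
    species_id = vapply(parts, `[`, character(1), 1L),
    genome_id = vapply(parts, `[`, character(1), 2L),
    orf_id = vapply(parts, `[`, character(1), 3L),
    seq = as.character(seqs, use.names = FALSE),
    label = ifelse(nf >= 4L,
                   as.integer(vapply(parts, function(p)
                     if (length(p) >= 4L) p[4L] else NA_character_,
                     character(1))),
                   NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Write ORF sequences to FASTA
#'
#' Ids are \code{species|genome|orf} plus \code{|label} when a label column
#' is present; sequence lines wrap at 70 columns.
#'
#' @param orfs ORF table (see [read_orf_fasta()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  ids <- paste(orfs$species_id, orfs$genome_id, orfs$orf_id, sep = "|")
  if (!is.null(orfs$label) && !anyNA(orfs$label))
    ids <- paste(ids, orfs$label, sep = "|")
  x <- Biostrings::DNAStringSet(orfs$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read / write a tab-separated bitscore table
#'
#' Three columns: \code{query}, \code{subject}, \code{score} — the format of
#' an all-vs-all search result reduced to bitscores.
#'
#' @param path TSV file path.
#' @return Data frame with columns \code{query}, \code{subject},
#'   \code{score}.
#' @export
read_bitscores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("query", "subject", "score") %in% names(df)))
  df
}

#' @rdname read_bitscores
#' @param bitscores Data frame with columns \code{query}, \code{subject},
#'   \code{score}.
#' @export
write_bitscores <- function(bitscores, path) {
  utils::write.table(bitscores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
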