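# End-to-end comparison pipeline: dataset construction per species, both
# classifiers x three representations x k-fold cross-validation, then the
# mixed-effect ANOVA, Tukey comparisons, variance F-tests and score-density
# summaries. File-driven: every stage can read and write the package's
# FASTA/TSV formats, and a thin command-line wrapper lives in
# inst/scripts/orfclass.

#' Configuration of a comparison run
#'
#' @param fasta_dir Directory of per-genome FASTA files (ids
#'   \code{species|genome|orf}), or NULL when \code{simulate} is given.
#' @param bitscore_tsv Optional precomputed bitscore TSV (query, subject,
#'   score); when NULL the toy k-mer scorer is used.
#' @param out_dir Output directory for report files (created if missing);
#'   NULL writes nothing.
#' @param simulate Optional [simulation_config()] replacing file input.
#' @param t Distance threshold for Positives (default 0.3).
#' @param cap Positive cap per species (default 400).
#' @param folds Cross-validation folds (default 10).
#' @param methods,representations Subsets to compare.
#' @param K Named list/vector of maximum orders per representation;
#'   defaults to [default_order()] values.
#' @param A_max,gamma_grid,inner_folds CPPLS controls.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A \code{run_config} list.
#' @export
run_config <- function(fasta_dir = NULL, bitscore_tsv = NULL, out_dir = NULL,
                       simulate = NULL, t = 0.3, cap = 400L, folds = 10L,
                       methods = c("imm", "cppls"),
                       representations = c("codon", "protein", "dna"),
                       K = NULL, A_max = 10L,
                       gamma_grid = sort(unique(c(0.5, (1:10) / 11))),
                       inner_folds = 5L, seed = 1L) {
  if (is.null(fasta_dir) && is.null(simulate))
    stop("either fasta_dir or simulate must be given")
  K_def <- c(dna = default_order("dna"), codon = default_order("codon"),
             protein = default_order("protein"))
  if (!is.null(K)) K_def[names(K)] <- unlist(K)
  structure(
    list(fasta_dir = fasta_dir, bitscore_tsv = bitscore_tsv,
         out_dir = out_dir, simulate = simulate, t = t, cap = cap,
         folds = folds, methods = methods,
         representations = representations, K = K_def, A_max = A_max,
         gamma_grid = gamma_grid, inner_folds = inner_folds,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname run_compare
#' @export
read_performance_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run the full method-by-representation comparison
#'
#' For every species: build the Positive/Negative dataset (HCO clustering on
#' bitscores, out-of-frame Negatives), run each requested classifier on each
#' representation under stratified cross-validation, and finally evaluate
#' the pooled fold records with the arcsine-transformed balanced
#' mixed-effect ANOVA, Tukey comparisons (methods, representations and
#' their cells) and per-cell variance F-tests against the reference cell.
#'
#' @param config A [run_config()].
#' @return List: \code{performance} (fold-level records), \code{cells},
#'   \code{anova} (NULL when fewer than 2 species), \code{tukey},
#'   \code{variance_tests}, \code{densities} (per species x method score
#'   summaries for the codon representation), \code{datasets} (per-species
#'   Positive/Negative counts), \code{seed}. When \code{out_dir} is set the
#'   tables are also written as TSV (\code{performance.tsv},
#'   \code{anova.tsv}, \code{tukey_*.tsv}, \code{clusters.tsv},
#'   \code{folds.tsv}, plus Positive/Negative FASTA per species).
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[orfclass %6.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(fmt, ...)))
  }
  if (!is.null(config$simulate)) {
    log_stage("simulating pangenome (%d species, seed %d)",
              config$simulate$n_species, config$simulate$seed)
    pan <- generate_pangenome(config$simulate)
    orfs_all <- pan$orfs
  } else {
    files <- list.files(config$fasta_dir, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files in ", config$fasta_dir)
    orfs_all <- do.call(rbind, lapply(files, read_orf_fasta))
  }
  bitscores_all <- if (!is.null(config$bitscore_tsv))
    read_bitscores(config$bitscore_tsv) else NULL

  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  species_ids <- unique(orfs_all$species_id)
  perf <- list()
  clusters <- list()
  fold_rows <- list()
  densities <- list()
  counts <- list()
  for (si in seq_along(species_ids)) {
    sp <- species_ids[si]
    sp_orfs <- orfs_all[orfs_all$species_id == sp, , drop = FALSE]
    sp_seed <- config$seed + 1000L * si
    log_stage("species %s: dataset construction (%d ORFs)", sp, nrow(sp_orfs))
    sp_scores <- if (is.null(bitscores_all)) NULL else
      bitscores_all[bitscores_all$query %in% sp_orfs$orf_id, , drop = FALSE]
    ds <- build_species_dataset(sp_orfs, t = config$t, cap = config$cap,
                                seed = sp_seed, bitscores = sp_scores)
    counts[[sp]] <- data.frame(species = sp, hcos = nrow(ds$hcos),
                               positives = nrow(ds$positives),
                               negatives = nrow(ds$negatives),
                               stringsAsFactors = FALSE)
    clusters[[sp]] <- data.frame(
      species = sp, cluster_id = ds$hcos$cluster_id,
      medoid = ds$hcos$medoid_id,
      members = vapply(ds$hcos$members, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
    fold <- split_folds(ds$dataset$label, folds = config$folds,
                        seed = sp_seed + 1L)
    fold_rows[[sp]] <- data.frame(species = sp, orf_id = ds$dataset$orf_id,
                                  fold = fold, stringsAsFactors = FALSE)
    if (!is.null(out)) {
      write_orf_fasta(ds$dataset[, c("species_id", "genome_id", "orf_id",
                                     "seq", "label")],
                      file.path(out, paste0(sp, "_dataset.fasta")))
    }
    for (method in config$methods) {
      for (rep_ in config$representations) {
        log_stage("species %s: %s / %s cross-validation", sp, method, rep_)
        perf[[paste(sp, method, rep_)]] <- run_cv(
          ds$dataset, method = method, representation = rep_,
          folds = config$folds, seed = sp_seed + 1L,
          K = config$K[[rep_]], A_max = config$A_max,
          gamma_grid = config$gamma_grid, inner_folds = config$inner_folds
        )
      }
    }
    if ("codon" %in% config$representations) {
      dens <- species_score_densities(ds$dataset, config, sp_seed + 1L)
      densities[[sp]] <- cbind(species = sp, dens)
    }
  }
  performance <- do.call(rbind, c(perf, list(make.row.names = FALSE)))
  cells <- performance_cells(performance)
  anova <- NULL
  tukey <- list()
  if (length(species_ids) >= 2L &&
      length(config$methods) == 2L && length(config$representations) == 3L) {
    log_stage("mixed-effect ANOVA over %d species", length(species_ids))
    anova <- mixed_anova(cells)
    ms_res <- anova$table$mean_sq[anova$table$term == "Residual"]
    df_res <- anova$table$df[anova$table$term == "Residual"]
    S <- length(species_ids)
    tukey$method <- tukey_hsd(tapply(cells$z, cells$method, mean),
                              ms_res, df_res, 3L * S)
    tukey$representation <- tukey_hsd(tapply(cells$z, cells$representation, mean),
                                      ms_res, df_res, 2L * S)
    cell_means <- tapply(cells$z, paste(cells$method, cells$representation,
                                        sep = ":"), mean)
    tukey$cell <- tukey_hsd(cell_means, ms_res, df_res, S)
  }
  variance_tests <- compare_cell_variances(performance)
  densities <- if (length(densities) > 0L)
    do.call(rbind, c(densities, list(make.row.names = FALSE))) else NULL

  result <- list(performance = performance, cells = cells, anova = anova,
                 tukey = tukey, variance_tests = variance_tests,
                 densities = densities,
                 datasets = do.call(rbind, c(counts, list(make.row.names = FALSE))),
                 seed = config$seed)
  if (!is.null(out)) {
    write_tsv(performance, file.path(out, "performance.tsv"))
    write_tsv(do.call(rbind, c(clusters, list(make.row.names = FALSE))),
              file.path(out, "clusters.tsv"))
    write_tsv(do.call(rbind, c(fold_rows, list(make.row.names = FALSE))),
              file.path(out, "folds.tsv"))
    if (!is.null(anova)) {
      write_tsv(anova$table, file.path(out, "anova.tsv"))
      for (nm in names(tukey))
        write_tsv(tukey[[nm]], file.path(out, paste0("tukey_", nm, ".tsv")))
    }
    if (!is.null(variance_tests))
      write_tsv(variance_tests, file.path(out, "variance_tests.tsv"))
    if (!is.null(densities))
      write_tsv(densities, file.path(out, "score_densities.tsv"))
    writeLines(c(sprintf("seed\t%d", config$seed),
                 sprintf("t\t%g", config$t),
                 sprintf("cap\t%d", config$cap),
                 sprintf("folds\t%d", config$folds)),
               file.path(out, "run_config.tsv"))
  }
  log_stage("done")
  result
}

# codon-representation score summaries on a single held-out fold per method
species_score_densities <- function(dataset, config, seed) {
  fold <- split_folds(dataset$label, folds = config$folds, seed = seed)
  tr <- fold != 1L
  te <- !tr
  rows <- list()
  if ("imm" %in% config$methods) {
    model <- imm_train(dataset[tr, , drop = FALSE], "codon",
                       K = config$K[["codon"]])
    s <- imm_score(model, dataset[te, , drop = FALSE])
    sd_ <- score_densities(s[, 1L] - s[, 2L], dataset$label[te])
    rows$imm <- data.frame(method = "imm", overlap = sd_$overlap,
                           mean_pos = mean(sd_$positive),
                           mean_neg = mean(sd_$negative),
                           stringsAsFactors = FALSE)
  }
  if ("cppls" %in% config$methods) {
    X <- word_feature_matrix(dataset$seq, "codon", config$K[["codon"]],
                             short_sequence = "zero")
    model <- cppls_fit(X[tr, , drop = FALSE], dataset$label[tr],
                       A_max = config$A_max, gamma_grid = config$gamma_grid,
                       inner_folds = config$inner_folds, seed = seed)
    s <- cppls_predict_score(model, X[te, , drop = FALSE])
    sd_ <- score_densities(s, dataset$label[te])
    rows$cppls <- data.frame(method = "cppls", overlap = sd_$overlap,
                             mean_pos = mean(sd_$positive),
                             mean_neg = mean(sd_$negative),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# two-sided variance F-test of every method x representation cell against
# the cell with the smallest variance (fold-level percent correct)
compare_cell_variances <- function(performance) {
  key <- paste(performance$method, performance$representation, sep = ":")
  groups <- split(performance$percent_correct, key)
  groups <- groups[vapply(groups, function(g)
    length(g) >= 2L && stats::var(g) > 0, logical(1))]
  if (length(groups) < 2L) return(NULL)
  vars <- vapply(groups, stats::var, numeric(1))
  ref <- names(which.min(vars))
  rows <- lapply(setdiff(names(groups), ref), function(nm) {
    ft <- variance_f_test(groups[[nm]], groups[[ref]])
    data.frame(cell = nm, reference = ref, F = ft$F, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
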