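# Cross-validated method comparison and its statistical evaluation.

fold_metrics <- function(truth, predicted) {
  pos <- truth == 1L
  neg <- truth == -1L
  c(
    percent_correct = 100 * mean(predicted == truth),
    sensitivity = if (any(pos)) 100 * mean(predicted[pos] == 1L) else NA_real_,
    specificity = if (any(neg)) 100 * mean(predicted[neg] == -1L) else NA_real_
  )
}

#' Cross-validated classification performance for one species
#'
#' Splits the labeled ORFs into stratified folds, trains the chosen
#' classifier on all but one fold and tests on the held-out fold, and
#' reports per-fold percent correct, sensitivity (Positives identified) and
#' specificity (Negatives identified).
#'
#' @param orfs Labeled ORF table (columns \code{seq}, \code{label}, and
#'   \code{species_id} used for the report).
#' @param method \code{"imm"} or \code{"cppls"}.
#' @param representation \code{"dna"}, \code{"codon"} or \code{"protein"}.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Seed for the fold split (and the CPPLS inner component
#'   selection, derived from it).
#' @param K Maximum order / word length minus one; defaults to
#'   [default_order()] of the representation.
#' @param A_max,gamma_grid,inner_folds CPPLS controls, see [cppls_fit()].
#' @param imm_prior Prior log-odds added to the IMM score difference before
#'   thresholding (see [imm_classify()]); 0 keeps the pure likelihood-ratio
#'   rule, \code{log(1/5)} encodes the 1:5 Positive:Negative design ratio.
#' @return Data frame with one row per fold: \code{species}, \code{method},
#'   \code{representation}, \code{fold}, \code{percent_correct},
#'   \code{sensitivity}, \code{specificity}.
#' @export
run_cv <- function(orfs, method = c("imm", "cppls"),
                   representation = c("codon", "dna", "protein"),
                   folds = 10L, seed = NULL, K = NULL,
                   A_max = 10L, gamma_grid = sort(unique(c(0.5, (1:10) / 11))),
                   inner_folds = 5L, imm_prior = 0) {
  method <- match.arg(method)
  representation <- match.arg(representation)
  if (is.null(K)) K <- default_order(representation)
  species <- if (!is.null(orfs$species_id)) orfs$species_id[1L] else NA_character_
  fold <- split_folds(orfs$label, folds = folds, seed = seed)

  X <- NULL
  if (method == "cppls") {
    seqs <- as_representation(orfs$seq, representation)
    X <- word_feature_matrix(seqs, representation, K, normalize = TRUE,
                             short_sequence = "zero")
  }
  records <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- !tr
    pred <- if (method == "imm") {
      model <- imm_train(orfs[tr, , drop = FALSE], representation, K = K)
      imm_classify(model, orfs[te, , drop = FALSE], prior_logodds = imm_prior)
    } else {
      model <- cppls_fit(X[tr, , drop = FALSE], orfs$label[tr], A_max = A_max,
                         gamma_grid = gamma_grid, inner_folds = inner_folds,
                         seed = if (is.null(seed)) NULL else seed + f)
      cppls_classify(model, X[te, , drop = FALSE])
    }
    m <- fold_metrics(orfs$label[te], pred)
    records[[f]] <- data.frame(
      species = species, method = method, representation = representation,
      fold = f, percent_correct = m[["percent_correct"]],
      sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, records)
}

#' Per-class score samples and their density overlap
#'
#' Splits classifier scores by true class and measures how much the two
#' kernel-density estimates overlap (shared area, 1 = indistinguishable,
#' 0 = disjoint supports) — the quantity visualized by score-density plots.
#'
#' @param scores Numeric scores (IMM: Positive minus Negative
#'   log-probability; CPPLS: fitted value).
#' @param labels True +1 / -1 labels.
#' @param n_grid Grid size of the common density grid.
#' @return List: \code{positive}, \code{negative} (score samples),
#'   \code{overlap} (shared KDE area).
#' @export
score_densities <- function(scores, labels, n_grid = 512L) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == -1L]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  rng <- range(scores)
  # widen the grid past the kernels' reach so both KDEs integrate to ~1 on it
  bw <- max(stats::bw.nrd0(pos), stats::bw.nrd0(neg))
  pad <- diff(rng) * 0.2 + 4 * bw + 1e-8
  from <- rng[1L] - pad
  to <- rng[2L] + pad
  dp <- stats::density(pos, from = from, to = to, n = n_grid)
  dn <- stats::density(neg, from = from, to = to, n = n_grid)
  dx <- dp$x[2L] - dp$x[1L]
  list(positive = pos, negative = neg,
       overlap = sum(pmin(dp$y, dn$y)) * dx)
}

#' Arcsine square-root transform of a percentage
#'
#' \eqn{z = \arcsin\sqrt{y/100}} (radians, range \eqn{[0, \pi/2]}), the
#' variance-stabilizing transform applied to percent-correct values before
#' the mixed-effect ANOVA.
#'
#' @param y Performance in percent, within [0, 100].
#' @return Transformed value(s) z.
#' @examples
#' transform_performance(c(0, 50, 100))  # 0, pi/4, pi/2
#' @export
transform_performance <- function(y) {
  if (any(y < 0 | y > 100)) stop("performance must be in [0, 100]")
  asin(sqrt(y / 100))
}

#' Balanced mixed-effect ANOVA of transformed performance
#'
#' Fits \eqn{z_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + s_k +
#' e_{ijk}} with fixed method (i = 1..2) and representation (j = 1..3)
#' effects and a random species effect (k = 1..S), on a complete balanced
#' table with one (fold-averaged) value per cell. Sums of squares come from
#' [stats::aov()]; every term's F statistic is taken against the residual
#' mean square. Variance components are method-of-moments estimates:
#' \eqn{\hat\sigma_e^2 = MS_{res}}, \eqn{\hat\sigma_s^2 = \max(0,
#' (MS_{species} - MS_{res})/6)} (6 observations per species).
#'
#' @param cells Data frame with columns \code{method}, \code{representation},
#'   \code{species} and \code{z} (transformed performance), one row per
#'   cell. [performance_cells()] builds it from fold-level records.
#' @return A \code{mixed_anova} object: \code{table} (term, sum_sq, df,
#'   mean_sq, F_value, p_value), \code{sigma_s}, \code{sigma_e},
#'   \code{n_species}.
#' @export
mixed_anova <- function(cells) {
  need <- c("method", "representation", "species", "z")
  if (!all(need %in% names(cells))) stop("cells must have columns ",
                                         paste(need, collapse = ", "))
  cells$method <- factor(cells$method)
  cells$representation <- factor(cells$representation)
  cells$species <- factor(cells$species)
  S <- nlevels(cells$species)
  n_cells <- nlevels(cells$method) * nlevels(cells$representation) * S
  if (nrow(cells) != n_cells ||
      any(table(cells$method, cells$representation, cells$species) != 1L))
    stop("cells must form a complete balanced table with one value per cell")
  fit <- stats::aov(z ~ method * representation + species, data = cells)
  tab <- summary(fit)[[1L]]
  term <- trimws(rownames(tab))
  get <- function(name, col) tab[match(name, term), col]
  terms_out <- c("method", "representation", "method:representation",
                 "species", "Residuals")
  pretty <- c("Method", "Sequence", "Method:Sequence", "Species", "Residual")
  sum_sq <- vapply(terms_out, get, numeric(1), col = "Sum Sq")
  df <- vapply(terms_out, get, numeric(1), col = "Df")
  mean_sq <- sum_sq / df
  ms_res <- mean_sq[[5L]]
  df_res <- df[[5L]]
  F_value <- c(mean_sq[1:4] / ms_res, NA_real_)
  p_value <- c(stats::pf(F_value[1:4], df[1:4], df_res, lower.tail = FALSE),
               NA_real_)
  out <- list(
    table = data.frame(
      term = pretty, sum_sq = unname(sum_sq), df = unname(df),
      mean_sq = unname(mean_sq), F_value = unname(F_value),
      p_value = unname(p_value), stringsAsFactors = FALSE
    ),
    sigma_e = sqrt(ms_res),
    sigma_s = sqrt(max(0, (mean_sq[[4L]] - ms_res) / 6)),
    n_species = S
  )
  class(out) <- "mixed_anova"
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Balanced mixed-effect ANOVA (fixed: method, representation; random: species)\n")
  tab <- x$table
  tab$sum_sq <- round(tab$sum_sq, 4)
  tab$mean_sq <- round(tab$mean_sq, 4)
  tab$F_value <- round(tab$F_value, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("sigma_s = %.4f, sigma_e = %.4f (%d species)\n",
              x$sigma_s, x$sigma_e, x$n_species))
  invisible(x)
}

#' Fold-averaged, transformed ANOVA cells from fold-level records
#'
#' Averages percent-correct over folds within each species x method x
#' representation cell and applies [transform_performance()].
#'
#' @param records Fold-level performance table from [run_cv()] (possibly
#'   row-bound over species, methods and representations).
#' @return Data frame of cells suitable for [mixed_anova()].
#' @export
performance_cells <- function(records) {
  agg <- stats::aggregate(percent_correct ~ method + representation + species,
                          data = records, FUN = mean)
  data.frame(
    method = agg$method, representation = agg$representation,
    species = agg$species, z = transform_performance(agg$percent_correct),
    stringsAsFactors = FALSE
  )
}

#' Tukey honestly-significant-difference comparisons
#'
#' Adjusted p-values for all pairwise differences of balanced group means,
#' based on the studentized range distribution with the residual mean
#' square of the surrounding ANOVA.
#'
#' @param means Named vector of group means.
#' @param ms_residual Residual mean square.
#' @param df_residual Residual degrees of freedom (>= 1).
#' @param n_per_group Observations behind each mean (balanced).
#' @return Data frame: \code{group_a}, \code{group_b}, \code{diff},
#'   \code{p_adj}.
#' @export
tukey_hsd <- function(means, ms_residual, df_residual, n_per_group) {
  if (df_residual < 1) stop("df_residual must be >= 1")
  if (length(means) < 2L) stop("need at least two groups")
  if (is.null(names(means))) names(means) <- seq_along(means)
  g <- length(means)
  se <- sqrt(ms_residual / n_per_group)
  pairs <- utils::combn(names(means), 2L)
  diffs <- means[pairs[2L, ]] - means[pairs[1L, ]]
  qstat <- abs(diffs) / se
  data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ], diff = unname(diffs),
    p_adj = stats::ptukey(qstat, nmeans = g, df = df_residual,
                          lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Two-sided F-test comparing two performance variances
#'
#' \eqn{F = s_a^2 / s_b^2} on (n_a - 1, n_b - 1) degrees of freedom, via
#' [stats::var.test()].
#'
#' @param sample_a,sample_b Numeric performance samples (length >= 2).
#' @return List: \code{F}, \code{df}, \code{p_value}.
#' @export
variance_f_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("both samples need at least 2 values")
  if (stats::var(sample_b) == 0)
    stop("degenerate: zero variance in the denominator sample")
  ht <- stats::var.test(sample_a, sample_b)
  list(F = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Performance table with planted method and representation effects
#'
#' Generates one transformed-performance value per cell of a 2-method x
#' 3-representation x S-species design from the mixed-effect model itself:
#' fixed effects as supplied, species effects N(0, sigma_s^2), residuals
#' N(0, sigma_e^2). Used to study the power of [mixed_anova()] against
#' known ground truth.
#'
#' @param n_species Number of species S.
#' @param mu Overall mean of transformed performance.
#' @param method_effect Effect (+/- half of it per method level).
#' @param representation_effects Length-3 deviations, must sum to 0.
#' @param interaction_effect Size of a method-by-representation interaction
#'   placed on the (method 2, representation 1) cell pattern.
#' @param sigma_s,sigma_e Species and residual standard deviations.
#' @param seed Optional seed.
#' @return Data frame of cells for [mixed_anova()].
#' @export
simulate_performance_table <- function(n_species = 12L, mu = 1.2,
                                       method_effect = 0.1,
                                       representation_effects = c(0.05, 0, -0.05),
                                       interaction_effect = 0,
                                       sigma_s = 0.077, sigma_e = 0.049,
                                       seed = NULL) {
  stopifnot(length(representation_effects) == 3L)
  if (abs(sum(representation_effects)) > 1e-12)
    stop("representation_effects must sum to 0")
  with_seed(seed, {
    species <- sprintf("sp%02d", seq_len(n_species))
    s_k <- stats::rnorm(n_species, 0, sigma_s)
    names(s_k) <- species
    grid <- expand.grid(method = c("imm", "cppls"),
                        representation = c("codon", "protein", "dna"),
                        species = species, stringsAsFactors = FALSE)
    alpha <- ifelse(grid$method == "cppls", method_effect / 2, -method_effect / 2)
    beta <- representation_effects[match(grid$representation,
                                         c("codon", "protein", "dna"))]
    ab <- interaction_effect *
      ifelse(grid$method == "cppls", 1, -1) *
      ifelse(grid$representation == "codon", 2 / 3, -1 / 3)
    grid$z <- mu + alpha + beta + ab + s_k[grid$species] +
      stats::rnorm(nrow(grid), 0, sigma_e)
    grid
  })
}
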