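# Interpolated Markov model classifier.
#
# Per class (Positive / Negative) a family of Markov chains of orders 0..K is
# fitted with m/4 pseudo-counts, and the chains are combined into one
# predictive distribution P(symbol | context) = sum_k w_k P_k(symbol | last k
# symbols) with convex weights w estimated by EM on the training data. For
# the frame-stratified DNA alphabet each order keeps three transition sets,
# one per codon position of the target symbol; the pretext crosses frames as
# the chain walks the sequence nucleotide by nucleotide.

encode_many <- function(sequences, alphabet) {
  lapply(sequences, encode_units, alphabet = alphabet)
}

# Empirical 0-order target distribution(s); uniform only for an empty set.
# For dna one distribution per target codon position. Kept exactly empirical
# so that the pseudo-count spread leaves observed 0-order frequencies at
# their maximum-likelihood values (fixed-point identity); strict positivity
# of fitted chains is restored by a negligible floor in fit_chain.
zero_order_distribution <- function(unit_seqs, alphabet) {
  B <- alphabet$n_symbols
  one <- function(targets) {
    cnt <- tabulate(targets + 1L, nbins = B)
    m <- sum(cnt)
    if (m == 0L) return(rep(1 / B, B))
    cnt / m
  }
  if (alphabet$frame_stratified) {
    lapply(1:3, function(f) {
      one(unlist(lapply(unit_seqs, function(u) {
        t_idx <- which((seq_along(u) - 1L) %% 3L == (f - 1L))
        u[t_idx]
      })))
    })
  } else {
    one(unlist(unit_seqs))
  }
}

#' Fit one fixed-order Markov chain with m/4 pseudo-counts
#'
#' Transition probabilities are maximum-likelihood estimates from the pooled
#' (pretext, target) counts of one class, stabilized by pseudo-counts: with
#' m observed transitions in a transition set, m/4 pseudo-observations are
#' added, spread evenly over pretext rows and over targets according to the
#' class's 0-order distribution. Every fitted probability is therefore
#' strictly positive.
#'
#' @param sequences Character vector of preprocessed sequences in the
#'   alphabet's units, or a list of pre-encoded integer vectors.
#' @param alphabet An [alphabet()] object or name.
#' @param k Chain order (>= 0).
#' @param pseudo_fraction Pseudo mass as a fraction of m (default 1/4).
#' @return A \code{transition_model}: order, alphabet name, and probability
#'   matrix (pretext rows x target columns; for dna a list of three such
#'   matrices, one per target codon position).
#' @export
fit_chain <- function(sequences, alphabet, k, pseudo_fraction = 0.25) {
  alphabet <- as_alphabet(alphabet)
  unit_seqs <- if (is.character(sequences)) {
    encode_many(sequences, alphabet)
  } else sequences
  if (length(unit_seqs) == 0L || all(lengths(unit_seqs) == 0L))
    stop("empty training set")
  B <- alphabet$n_symbols
  if (any(lengths(unit_seqs) < k + 1L))
    stop("every training sequence must have at least k+1 units")
  p0 <- zero_order_distribution(unit_seqs, alphabet)

  rows <- B^k
  count_set <- function(pretext, target) {
    # pooled counts as a rows x B matrix
    matrix(tabulate(pretext * B + target + 1L, nbins = rows * B),
           nrow = rows, ncol = B, byrow = TRUE)
  }
  pretext_target <- function(u) {
    n <- length(u)
    if (n <= k) return(NULL)
    if (k == 0L) {
      list(pretext = rep(0L, n), target = u, t = seq_len(n))
    } else {
      codes <- u
      if (k >= 2L) for (L in 2:k) codes <- codes[seq_len(n - L + 1L)] * B + u[L:n]
      list(pretext = codes[seq_len(n - k)], target = u[(k + 1L):n],
           t = (k + 1L):n)
    }
  }
  pt <- lapply(unit_seqs, pretext_target)
  pt <- pt[!vapply(pt, is.null, logical(1))]
  finalize <- function(counts, p0_set) {
    m <- sum(counts)
    pseudo <- (m * pseudo_fraction / nrow(counts)) *
      matrix(p0_set, nrow = nrow(counts), ncol = B, byrow = TRUE)
    if (m == 0) pseudo[] <- matrix(p0_set, nrow(counts), B, byrow = TRUE)
    aug <- counts + pseudo
    P <- aug / rowSums(aug)
    if (any(P == 0)) {
      # symbol entirely unseen in training: floor keeps every probability
      # strictly positive while perturbing seen ones by O(1e-12) at most
      P <- P + 1e-12
      P <- P / rowSums(P)
    }
    P
  }
  if (alphabet$frame_stratified) {
    prob <- lapply(1:3, function(f) {
      pretext <- unlist(lapply(pt, function(x) x$pretext[(x$t - 1L) %% 3L == f - 1L]))
      target <- unlist(lapply(pt, function(x) x$target[(x$t - 1L) %% 3L == f - 1L]))
      finalize(count_set(as.numeric(pretext), target), p0[[f]])
    })
  } else {
    pretext <- unlist(lapply(pt, `[[`, "pretext"))
    target <- unlist(lapply(pt, `[[`, "target"))
    prob <- finalize(count_set(as.numeric(pretext), target), p0)
  }
  structure(
    list(order = as.integer(k), alphabet = alphabet$name,
         frame_stratified = alphabet$frame_stratified, prob = prob),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  np <- if (x$frame_stratified) sum(vapply(x$prob, length, numeric(1))) else length(x$prob)
  cat(sprintf("<transition_model> %s order %d (%s probabilities)\n",
              x$alphabet, x$order, format(np, big.mark = ",")))
  invisible(x)
}

# probability of units[t] under a fixed-order chain, for t > order (NA below)
chain_prob_vector <- function(chain, units) {
  k <- chain$order
  n <- length(units)
  out <- rep(NA_real_, n)
  if (n <= k) return(out)
  B <- if (chain$frame_stratified) 4L else ncol(chain$prob)
  if (k == 0L) {
    pretext <- rep(0L, n - k)
  } else {
    codes <- as.numeric(units)
    if (k >= 2L) for (L in 2:k) codes <- codes[seq_len(n - L + 1L)] * B + units[L:n]
    pretext <- codes[seq_len(n - k)]
  }
  t_idx <- (k + 1L):n
  target <- units[t_idx]
  if (chain$frame_stratified) {
    frame <- (t_idx - 1L) %% 3L + 1L
    for (f in 1:3) {
      sel <- frame == f
      if (any(sel))
        out[t_idx[sel]] <- chain$prob[[f]][cbind(pretext[sel] + 1, target[sel] + 1L)]
    }
  } else {
    out[t_idx] <- chain$prob[cbind(pretext + 1, target + 1L)]
  }
  out
}

# n x (K+1) matrix of per-order component probabilities for one sequence;
# at position t <= k, component k backs off to the order-(t-1) chain, so the
# first symbols are scored with whatever pretext is available.
component_matrix <- function(chains, units) {
  K <- length(chains) - 1L
  n <- length(units)
  if (n == 0L) stop("sequence has no units to score")
  M <- vapply(chains, chain_prob_vector, numeric(n), units = units)
  M <- matrix(M, nrow = n)
  if (K >= 1L) {
    for (t in seq_len(min(K, n))) {
      M[t, t:(K + 1L)] <- M[t, t]
    }
  }
  M
}

#' Estimate interpolation weights by EM
#'
#' Maximizes the training log-likelihood of the mixture
#' \eqn{P(x_t | \mathrm{context}) = \sum_k w_k P_k(x_t | \mathrm{pretext}_k)}
#' over convex weights w. Because the component distributions are fixed the
#' likelihood is concave in w and EM converges to the global optimum
#' regardless of the (uniform) initialization; every iteration weakly
#' increases the likelihood.
#'
#' @param chains List of [fit_chain()] models for orders 0..K of one class.
#' @param sequences Training sequences of the same class (character vector
#'   in alphabet units or pre-encoded integer vectors).
#' @param tol Stop when the relative log-likelihood improvement,
#'   \code{(ll - ll_prev) / (1 + |ll|)}, falls below this.
#' @param max_iter Iteration cap; hitting it sets \code{converged = FALSE}.
#' @return List: \code{weights} (sums to 1), \code{loglik},
#'   \code{iterations}, \code{converged}.
#' @export
fit_interpolation_weights <- function(chains, sequences,
                                      tol = 1e-8, max_iter = 500L) {
  alphabet <- as_alphabet(chains[[1L]]$alphabet)
  unit_seqs <- if (is.character(sequences)) {
    encode_many(sequences, alphabet)
  } else sequences
  M <- do.call(rbind, lapply(unit_seqs, component_matrix, chains = chains))
  K1 <- ncol(M)
  w <- rep(1 / K1, K1)
  if (K1 == 1L)
    return(list(weights = 1, loglik = sum(log(M[, 1L])),
                iterations = 0L, converged = TRUE))
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- as.vector(M %*% w)
    ll <- sum(log(mix))
    if (is.finite(ll_prev) && (ll - ll_prev) / (1 + abs(ll)) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    w <- w * as.vector(crossprod(M, 1 / mix)) / nrow(M)
    w <- w / sum(w)
    if (iter >= max_iter) break
  }
  list(weights = w, loglik = ll, iterations = iter, converged = converged)
}

#' Train a two-class interpolated Markov model
#'
#' Fits chains of orders 0..K and their interpolation weights separately on
#' the Positive and Negative training sequences.
#'
#' @param orfs Labeled ORF table (columns \code{seq}, \code{label} with +1 /
#'   -1); \code{seq} must be preprocessed nucleotide sequences.
#' @param representation \code{"dna"}, \code{"codon"} or \code{"protein"}.
#' @param K Maximum chain order; defaults to [default_order()] of the
#'   representation.
#' @param pseudo_fraction Pseudo mass fraction m/4 by default.
#' @param tol,max_iter EM controls, see [fit_interpolation_weights()].
#' @return An \code{imm_model}: per-class chains and weights plus metadata.
#' @export
imm_train <- function(orfs, representation = c("codon", "dna", "protein"),
                      K = NULL, pseudo_fraction = 0.25,
                      tol = 1e-8, max_iter = 500L) {
  representation <- match.arg(representation)
  if (is.null(K)) K <- default_order(representation)
  alphabet <- alphabet(representation)
  stopifnot(all(orfs$label %in% c(-1L, 1L)))
  if (!any(orfs$label == 1L) || !any(orfs$label == -1L))
    stop("training data must contain both classes")
  seqs <- as_representation(orfs$seq, representation)
  fit_class <- function(cls) {
    unit_seqs <- encode_many(seqs[orfs$label == cls], alphabet)
    chains <- lapply(0:K, function(k)
      fit_chain(unit_seqs, alphabet, k, pseudo_fraction))
    wfit <- fit_interpolation_weights(chains, unit_seqs, tol, max_iter)
    list(chains = chains, weights = wfit$weights, converged = wfit$converged,
         loglik = wfit$loglik)
  }
  structure(
    list(positive = fit_class(1L), negative = fit_class(-1L),
         representation = representation, K = as.integer(K),
         pseudo_fraction = pseudo_fraction),
    class = "imm_model"
  )
}

#' @export
print.imm_model <- function(x, ...) {
  cat(sprintf("<imm_model> %s, orders 0..%d\n", x$representation, x$K))
  cat("  positive weights:", signif(x$positive$weights, 3), "\n")
  cat("  negative weights:", signif(x$negative$weights, 3), "\n")
  invisible(x)
}

#' Log-probability scores of sequences under both class models
#'
#' @param model An \code{imm_model}.
#' @param orfs Labeled ORF table or character vector of preprocessed
#'   nucleotide sequences.
#' @return Matrix with columns \code{logP_positive}, \code{logP_negative},
#'   one row per sequence.
#' @export
imm_score <- function(model, orfs) {
  seqs <- if (is.data.frame(orfs)) orfs$seq else orfs
  seqs <- as_representation(seqs, model$representation)
  alphabet <- alphabet(model$representation)
  unit_seqs <- encode_many(seqs, alphabet)
  score_one <- function(u, side) {
    M <- component_matrix(side$chains, u)
    sum(log(as.vector(M %*% side$weights)))
  }
  out <- cbind(
    logP_positive = vapply(unit_seqs, score_one, numeric(1), side = model$positive),
    logP_negative = vapply(unit_seqs, score_one, numeric(1), side = model$negative)
  )
  out
}

#' Classify sequences with an interpolated Markov model
#'
#' Assigns +1 when the Positive log-probability exceeds the Negative one
#' (plus an optional prior log-odds term) and -1 otherwise; an exact tie is
#' called -1 (non-coding), the conservative choice.
#'
#' @inheritParams imm_score
#' @param prior_logodds Added to the score difference before thresholding;
#'   0 (default) is a pure likelihood-ratio rule. Use
#'   \code{log(n_pos / n_neg)} to incorporate the class ratio.
#' @return Integer vector of +1 / -1 labels.
#' @export
imm_classify <- function(model, orfs, prior_logodds = 0) {
  s <- imm_score(model, orfs)
  diff <- s[, "logP_positive"] - s[, "logP_negative"] + prior_logodds
  ifelse(diff > 0, 1L, -1L)
}

#' Serialize / restore an IMM model as JSON text
#'
#' @param model An \code{imm_model}.
#' @param path File path.
#' @return \code{path} (write) or the restored model (read).
#' @export
write_imm <- function(model, path) {
  ser_side <- function(side) {
    list(
      weights = side$weights,
      chains = lapply(side$chains, function(ch) {
        list(order = ch$order,
             prob = if (ch$frame_stratified) lapply(ch$prob, as.vector)
                    else as.vector(ch$prob))
      })
    )
  }
  obj <- list(
    format = "orfclass-imm", version = 1L,
    representation = model$representation, K = model$K,
    pseudo_fraction = model$pseudo_fraction,
    positive = ser_side(model$positive), negative = ser_side(model$negative)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imm
#' @export
read_imm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "orfclass-imm"))
    stop("not an orfclass IMM model file")
  alphabet <- alphabet(obj$representation)
  B <- alphabet$n_symbols
  obj$K <- as.integer(obj$K)
  de_side <- function(side) {
    chains <- lapply(seq_len(obj$K + 1L), function(i) {
      k <- i - 1L
      ch <- side$chains[[i]]
      prob <- if (alphabet$frame_stratified) {
        lapply(ch$prob, function(v)
          matrix(unlist(v, use.names = FALSE), nrow = 4L^k, ncol = 4L))
      } else {
        matrix(unlist(ch$prob, use.names = FALSE), nrow = B^k, ncol = B)
      }
      structure(list(order = k, alphabet = alphabet$name,
                     frame_stratified = alphabet$frame_stratified, prob = prob),
                class = "transition_model")
    })
    list(chains = chains,
         weights = unlist(side$weights, use.names = FALSE), converged = TRUE)
  }
  structure(
    list(positive = de_side(obj$positive), negative = de_side(obj$negative),
         representation = obj$representation, K = as.integer(obj$K),
         pseudo_fraction = obj$pseudo_fraction),
    class = "imm_model"
  )
}
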