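# Exact-gradient t-SNE (van der Maaten & Hinton 2008 formulation).
#
# High-dimensional neighbor probabilities are calibrated per point to a
# target perplexity by binary search on the Gaussian bandwidth; the 2-D map
# minimizes KL(P||Q) with a Student-t (1 df) kernel by gradient descent with
# early exaggeration, momentum schedule and adaptive per-parameter gains.
# The gradient is the exact O(n^2) one: at the library sizes this package
# targets (n of order 100-250) the Barnes-Hut approximation buys nothing,
# while the exact gradient is directly testable against the cost function.
# A theta parameter is accepted for configuration compatibility and recorded
# in the output, but does not affect the computation.

#' t-SNE parameter set
#'
#' @param perplexity target perplexity of the conditional neighbor
#'   distributions; must satisfy `perplexity < (n - 1) / 3`.
#' @param iterations gradient-descent iterations (>= 250).
#' @param learning_rate step size of the gradient update.
#' @param seed integer seed; combined with each point identifier to generate
#'   the initial coordinates, so determinism survives row reordering.
#' @param theta accepted for configuration compatibility (Barnes-Hut
#'   accuracy parameter); recorded but unused by the exact gradient.
#' @param out_dims output dimensionality (fixed at 2).
#' @param early_exaggeration factor multiplying P during the initial phase.
#' @param exaggeration_iters length of the early-exaggeration phase.
#' @param momentum_start,momentum_final,momentum_switch momentum schedule.
#' @return A list of class `tsne_params`.
#' @export
tsne_params <- function(perplexity = 30, iterations = 5000,
                        learning_rate = 200, seed = 1, theta = 0.5,
                        out_dims = 2, early_exaggeration = 12,
                        exaggeration_iters = 250,
                        momentum_start = 0.5, momentum_final = 0.8,
                        momentum_switch = 250) {
  stopifnot(perplexity > 0, iterations >= 250, learning_rate > 0, out_dims == 2)
  structure(list(perplexity = perplexity, iterations = as.integer(iterations),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 theta = theta, out_dims = 2L,
                 early_exaggeration = early_exaggeration,
                 exaggeration_iters = as.integer(exaggeration_iters),
                 momentum_start = momentum_start,
                 momentum_final = momentum_final,
                 momentum_switch = as.integer(momentum_switch)),
            class = "tsne_params")
}

#' Perplexity-calibrated joint probabilities
#'
#' For each point, binary-searches the Gaussian bandwidth so that the
#' Shannon entropy of the conditional distribution p(j|i) over squared
#' distances matches log(perplexity), then symmetrizes:
#' P_ij = (p(j|i) + p(i|j)) / (2n). P has zero diagonal and sums to 1.
#'
#' @param D symmetric distance matrix.
#' @param perplexity target perplexity, `< n`.
#' @param tol entropy tolerance of the bandwidth search.
#' @param max_iter maximum bisection steps per row.
#' @return Joint probability matrix with attribute `"beta"` (the fitted
#'   precisions 1 / (2 sigma_i^2)).
#' @export
perplexity_calibration <- function(D, perplexity, tol = 1e-6, max_iter = 100) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop_bitter("validation_error", "need at least 3 points")
  if (perplexity >= n) {
    stop_bitter("validation_error",
                sprintf("perplexity %.3g infeasible for n = %d", perplexity, n))
  }
  target <- log(perplexity)
  D2 <- D^2
  P <- matrix(0, n, n)
  beta <- numeric(n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    b <- 1; bmin <- -Inf; bmax <- Inf
    H <- NA_real_
    for (it in seq_len(max_iter)) {
      w <- exp(-di * b)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < tol) break
      if (H > target) { bmin <- b; b <- if (is.finite(bmax)) (b + bmax) / 2 else b * 2 }
      else            { bmax <- b; b <- if (is.finite(bmin)) (b + bmin) / 2 else b / 2 }
    }
    if (abs(H - target) >= max(tol, 1e-4)) {
      stop_bitter("calibration_error",
                  sprintf("bandwidth search did not converge for row %d", i), row = i)
    }
    w <- exp(-di * b)
    if (sum(w) == 0) {
      # bandwidth collapsed (perplexity -> 1): all mass on the nearest point
      w[which.min(di)] <- 1
    }
    P[i, -i] <- w / sum(w)
    beta[i] <- b
  }
  P <- (P + t(P)) / (2 * n)
  attr(P, "beta") <- beta
  P
}

# deterministic per-point seed: 31-bit polynomial hash of (seed, id)
hash_seed <- function(seed, id) {
  codes <- utf8ToInt(paste0(seed, ":", id))
  h <- 5381
  for (cc in codes) h <- (h * 33 + cc) %% 2147483629
  as.integer(h)
}

#' Run t-SNE gradient descent on a joint probability matrix
#'
#' Minimizes KL(P||Q) with a Student-t (1 degree of freedom) low-dimensional
#' kernel by gradient descent with early exaggeration, a momentum schedule
#' and adaptive gains. Initial coordinates are Gaussian at the conventional
#' 1e-4 scale, drawn per point from a seed hashed from (`params$seed`,
#' point id), so the result is deterministic and exactly equivariant under
#' input permutation (points are also processed in a canonical id order).
#'
#' @param P joint probability matrix from [perplexity_calibration()].
#' @param params a [tsne_params()] object.
#' @param ids optional point identifiers (default: rownames of `P`, else
#'   `1:n`); used for seeding and as rownames of the output coordinates.
#' @return An object of class `tsne_embedding`: list with `coords` (n x 2,
#'   column means zero), `kl_final`, `kl_trace` (KL recorded every 25
#'   iterations, exaggeration removed), and `params`.
#' @export
tsne_embed <- function(P, params = tsne_params(), ids = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (is.null(ids)) ids <- if (!is.null(rownames(P))) rownames(P) else as.character(seq_len(n))
  P <- unname(P)
  if (anyDuplicated(ids)) stop_bitter("validation_error", "duplicate point ids")
  # canonical processing order (sorted ids): together with per-id seeding this
  # makes the result exactly invariant to the order the rows arrive in
  ord <- order(ids, method = "radix")
  P <- P[ord, ord]
  ids_in <- ids
  ids <- ids[ord]
  Y <- t(vapply(ids, function(id) {
    set.seed(hash_seed(params$seed, id))
    stats::rnorm(2, sd = 1e-4)
  }, numeric(2)))
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pn <- pmax(P, 1e-18)
  kl_trace <- c()
  kl_of <- function(Q) sum(P[P > 0] * log(Pn[P > 0] / Q[P > 0]))
  for (it in seq_len(params$iterations)) {
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-18)
    Pe <- if (it <= params$exaggeration_iters) P * params$early_exaggeration else P
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    if (any(!is.finite(grad))) {
      stop_bitter("divergence_error",
                  sprintf("non-finite gradient at iteration %d", it), iteration = it)
    }
    mom <- if (it <= params$momentum_switch) params$momentum_start else params$momentum_final
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- mom * inc - params$learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it %% 25 == 0 || it == params$iterations) {
      kl <- kl_of(Q)
      if (!is.finite(kl)) {
        stop_bitter("divergence_error",
                    sprintf("non-finite KL at iteration %d", it), iteration = it)
      }
      kl_trace <- c(kl_trace, stats::setNames(kl, it))
    }
  }
  rownames(Y) <- ids
  Y <- Y[match(ids_in, ids), , drop = FALSE]   # back to input order
  colnames(Y) <- c("tsne0", "tsne1")
  structure(list(coords = Y, kl_final = unname(kl_trace[length(kl_trace)]),
                 kl_trace = kl_trace, params = params),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("<tsne_embedding> %d points, perplexity %.3g, %d iterations, final KL %.4f\n",
              nrow(x$coords), x$params$perplexity, x$params$iterations, x$kl_final))
  invisible(x)
}

#' Embed a dataset in 2-D chemical space
#'
#' Full composition: MACCS fingerprints of the canonical SMILES, pairwise
#' distances, perplexity calibration, t-SNE gradient descent. Coordinates
#' are keyed by compound_id.
#'
#' @param ds an `activity_dataset`.
#' @param params a [tsne_params()] object.
#' @param metric distance metric passed to [pairwise_distances()].
#' @return A `tsne_embedding` with rownames equal to the compound ids.
#' @export
embed_dataset <- function(ds, params = tsne_params(),
                          metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  n <- n_compounds(ds)
  feasible <- (n - 1) / 3
  if (params$perplexity >= feasible) {
    eff <- max(1, feasible * 0.999)
    warning(sprintf(
      "perplexity %.3g >= (n-1)/3 for n = %d; clamped to %.3g",
      params$perplexity, n, eff))
    params$perplexity <- eff
  }
  smiles <- stats::setNames(ds$compounds$smiles, ds$compounds$compound_id)
  fps <- maccs_fingerprint(smiles)
  D <- pairwise_distances(fps, metric = metric)
  P <- perplexity_calibration(D, params$perplexity)
  rownames(P) <- rownames(fps)
  tsne_embed(P, params, ids = ds$compounds$compound_id)
}

#' Write / read embedding coordinates
#'
#' CSV with columns `compound_id`, `tsne0`, `tsne1`; the read-back equals
#' the written coordinates.
#'
#' @param emb a `tsne_embedding`.
#' @param path output path.
#' @return `path` invisibly for the writer; a data.frame for the reader.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(compound_id = rownames(emb$coords),
                   tsne0 = emb$coords[, 1], tsne1 = emb$coords[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
}
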