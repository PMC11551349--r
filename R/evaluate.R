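# Ground-truth evaluation: spectral angle distance, Hungarian endmember
# matching, abundance MSE, the benchmark grid, and runtime profiling.

#' Spectral angle distance (SAD)
#'
#' The arccosine of the cosine similarity between two spectra, in radians.
#' Scale-invariant (`sad(a, c * b) == sad(a, b)` for `c > 0`) and symmetric.
#' The cosine is clipped to `[-1, 1]` before `acos` to absorb floating-point
#' roundoff (the training loss additionally keeps a small margin away from
#' the endpoints so gradients stay finite; see [training_loss()]).
#'
#' @param a,b Numeric vectors of equal length, not all-zero.
#' @return Angle in radians, `>= 0`.
#' @export
#' @examples
#' sad(c(1, 0), c(0, 1)) # pi / 2
sad <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    rmx_abort("SAD is undefined for a zero-norm spectrum.", "ramanmix_error_domain")
  }
  cs <- sum(a * b) / (na * nb)
  acos(min(max(cs, -1), 1))
}

# pairwise SAD between rows of two matrices -> nrow(A) x nrow(B)
sad_matrix <- function(A, B) {
  An <- A / sqrt(rowSums(A * A))
  Bn <- B / sqrt(rowSums(B * B))
  C <- An %*% t(Bn)
  acos(pmin(pmax(C, -1), 1))
}

# Hungarian algorithm (potentials / shortest augmenting path, O(n^3)) for a
# square or wide cost matrix; rows must be <= columns. Returns, for each
# row, the assigned column.
hungarian_lsap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}

#' Match estimated endmembers to ground truth
#'
#' Solves the optimal assignment of ground-truth endmembers to estimated
#' endmembers with the Hungarian algorithm, minimizing total spectral angle
#' distance. When more endmembers were extracted than exist in the ground
#' truth (`n > n_true`), the surplus estimates are left unmatched and only
#' the matched `n_true` pairs enter any downstream metric.
#'
#' @param est Estimated [endmember_set()] (`n x b`, `n >= n_true`).
#' @param truth Ground-truth [endmember_set()] (`n_true x b`).
#' @return A list of class `match_result`: `permutation` (for each truth
#'   index, the matched estimate index), `sad` (per-pair SAD, radians),
#'   `unmatched` (estimate indices not used), `total_sad`, `mean_sad`.
#' @export
match_endmembers <- function(est, truth) {
  stopifnot(inherits(est, "endmember_set"), inherits(truth, "endmember_set"))
  n_est <- nrow(est$signatures); n_true <- nrow(truth$signatures)
  if (n_est < n_true) {
    rmx_abort(sprintf("Need at least %d estimated endmembers, got %d.",
                      n_true, n_est), "ramanmix_error_param")
  }
  if (ncol(est$signatures) != ncol(truth$signatures)) {
    rmx_abort("Band counts of estimate and truth differ.", "ramanmix_error_dim")
  }
  cost <- sad_matrix(truth$signatures, est$signatures)  # n_true x n_est
  perm <- hungarian_lsap(cost)
  pair_sad <- cost[cbind(seq_len(n_true), perm)]
  structure(list(
    permutation = perm,
    sad = pair_sad,
    unmatched = setdiff(seq_len(n_est), perm),
    total_sad = sum(pair_sad),
    mean_sad = mean(pair_sad)
  ), class = "match_result")
}

#' @exportS3Method base::print
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched pairs, mean SAD %.4g rad\n",
              length(x$sad), x$mean_sad))
  invisible(x)
}

#' Abundance mean squared error
#'
#' Per spectrum, `MSE(alpha, alpha_hat) = (1/n) * ||alpha - alpha_hat||^2`
#' over the `n = n_true` ground-truth components; the reported value is the
#' mean over spectra. Estimated abundance columns must first be permuted into
#' ground-truth order, e.g. with the permutation from [match_endmembers()]
#' (pass it as `permutation`).
#'
#' @param truth Ground-truth [abundance_map()] (`N x n_true`).
#' @param est Estimated [abundance_map()] (`N x n`, `n >= n_true`).
#' @param permutation Optional integer vector mapping truth columns to
#'   estimate columns (from [match_endmembers()]); identity by default.
#' @return Mean per-spectrum MSE (scalar). The per-spectrum values are
#'   attached as attribute `"per_spectrum"`.
#' @export
abundance_mse <- function(truth, est, permutation = NULL) {
  At <- if (inherits(truth, "abundance_map")) truth$values else as.matrix(truth)
  Ae <- if (inherits(est, "abundance_map")) est$values else as.matrix(est)
  if (nrow(At) != nrow(Ae)) {
    rmx_abort("Abundance maps have different numbers of spectra.",
              "ramanmix_error_dim")
  }
  n_true <- ncol(At)
  permutation <- permutation %||% seq_len(n_true)
  if (length(permutation) != n_true || max(permutation) > ncol(Ae)) {
    rmx_abort("`permutation` must map every truth column to an estimate column.",
              "ramanmix_error_dim")
  }
  D <- At - Ae[, permutation, drop = FALSE]
  per <- rowSums(D * D) / n_true
  out <- mean(per)
  attr(out, "per_spectrum") <- per
  out
}

#' Score an unmixing result against a generation record
#'
#' Convenience wrapper: Hungarian-matches the estimated endmembers to the
#' ground truth and computes the matched mean SAD and the abundance MSE
#' under the same permutation.
#'
#' @param result An `unmixing_result` (see [unmix()]).
#' @param record A `generation_record` from [generate_raman_dataset()].
#' @return A one-row tibble: `method`, `mean_sad`, `abundance_mse`,
#'   `n_est`, `n_true`.
#' @export
evaluate_unmixing <- function(result, record) {
  stopifnot(inherits(record, "generation_record"))
  m <- match_endmembers(result$endmembers, record$endmembers)
  mse <- abundance_mse(record$abundances, result$abundances,
                       permutation = m$permutation)
  tibble::tibble(
    method = result$method %||% NA_character_,
    mean_sad = m$mean_sad,
    abundance_mse = as.numeric(mse),
    n_est = nrow(result$endmembers$signatures),
    n_true = nrow(record$endmembers$signatures)
  )
}

#' Enumerate the sugar-mixture factorial design
#'
#' Enumerates a full factorial design of `n_sugars` sugars, each pipetted at
#' one of the given volume levels into a fixed-volume well (topped up with
#' water), then discards combinations whose total sugar volume exceeds the
#' well volume as well as the all-water combination. With the default four
#' levels (0, 30, 75, 120 uL), four sugars and a 375 uL well this yields 240
#' distinct mixtures.
#'
#' @param levels Volume levels per sugar (uL).
#' @param n_sugars Number of sugar species.
#' @param well_volume Well capacity (uL).
#' @param sugars Optional sugar names (defaults to glucose, sucrose,
#'   fructose, maltose for `n_sugars = 4`).
#' @return A tibble with one row per admissible mixture: one volume column
#'   per sugar, `total_sugar_volume`, `water_volume`.
#' @export
sugar_mixture_design <- function(levels = c(0, 30, 75, 120), n_sugars = 4,
                                 well_volume = 375, sugars = NULL) {
  if (is.null(sugars)) {
    sugars <- if (n_sugars == 4) c("glucose", "sucrose", "fructose", "maltose")
              else paste0("sugar_", seq_len(n_sugars))
  }
  grid <- do.call(expand.grid, stats::setNames(rep(list(levels), n_sugars), sugars))
  total <- rowSums(grid)
  keep <- total <= well_volume & total > 0
  out <- tibble::as_tibble(grid[keep, , drop = FALSE])
  out$total_sugar_volume <- total[keep]
  out$water_volume <- well_volume - total[keep]
  out
}
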