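## Hyper-inverse Wishart distribution on decomposable graphs: sampling by
## clique-wise factorization and the marginal likelihood of mean-zero
## Gaussian data with the covariance integrated out. Parameterization
## follows the graphical-models convention HIW(delta, D): every clique
## margin Sigma_C has density |Sigma_C|^-((delta+2c)/2) exp(-tr(Sigma_C^-1
## D_C)/2), i.e. inverse Wishart with standard degrees of freedom
## nu = delta + c - 1 for a clique of size c.

.lmvgamma <- function(a, p) {
  if (p == 0) return(0)
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## log of the clique factor |D_c/2|^((delta+m-1)/2) / Gamma_m((delta+m-1)/2)
.log_h <- function(delta, Dc) {
  m <- nrow(Dc)
  if (m == 0) return(0)
  a <- (delta + m - 1) / 2
  ld <- if (m == 1) log(Dc[1] / 2) else
    2 * sum(log(diag(chol(Dc)))) - m * log(2)
  a * ld - .lmvgamma(a, m)
}

#' Log marginal likelihood of residuals under a hyper-inverse Wishart prior
#'
#' For n iid mean-zero q-variate Gaussian rows with crossproduct `S` and
#' covariance Sigma ~ HIW(delta, D) on the decomposable graph `adj`,
#' integrates Sigma out in closed form via the clique/separator
#' factorization.
#'
#' @param S q x q crossproduct of the residuals.
#' @param n number of rows.
#' @param adj adjacency matrix of the decomposable graph.
#' @param delta HIW degrees of freedom (> 2 for a finite prior mean).
#' @param D HIW scale matrix.
#' @return log marginal likelihood (a scalar).
#' @keywords internal
hiw_log_marginal <- function(S, n, adj, delta, D) {
  q <- nrow(S)
  dec <- clique_decomposition(adj)
  out <- -(n * q / 2) * log(2 * pi)
  for (cl in dec$cliques)
    out <- out + .log_h(delta, D[cl, cl, drop = FALSE]) -
      .log_h(delta + n, D[cl, cl, drop = FALSE] + S[cl, cl, drop = FALSE])
  for (sp in dec$separators) {
    if (length(sp) == 0) next
    out <- out - .log_h(delta, D[sp, sp, drop = FALSE]) +
      .log_h(delta + n, D[sp, sp, drop = FALSE] + S[sp, sp, drop = FALSE])
  }
  out
}

## Inverse Wishart draw in the standard convention (density
## |W|^-((nu+p+1)/2) exp(-tr(W^-1 Psi)/2)).
.riw <- function(nu, Psi) {
  K <- stats::rWishart(1, nu, chol2inv(chol(Psi)))[, , 1]
  chol2inv(chol(K))
}

#' Draw a covariance matrix from a hyper-inverse Wishart distribution
#'
#' Sequential clique-wise sampler: the first clique margin is inverse
#' Wishart; each later clique contributes its conditional given the
#' separator (an inverse Wishart for the Schur complement and a matrix
#' normal for the regression block), and the joint matrix is completed so
#' the precision has exact zeros off the graph.
#'
#' @param delta HIW degrees of freedom.
#' @param D q x q scale matrix.
#' @param adj adjacency matrix of the decomposable graph.
#' @return A q x q positive-definite matrix whose inverse vanishes on
#'   non-edges of `adj`.
#' @keywords internal
rhiw <- function(delta, D, adj) {
  q <- nrow(D)
  dec <- clique_decomposition(adj)
  Sigma <- matrix(0, q, q)
  c1 <- dec$cliques[[1]]
  Sigma[c1, c1] <- .riw(delta + length(c1) - 1, D[c1, c1, drop = FALSE])
  done <- c1
  if (length(dec$cliques) > 1) {
    for (j in 2:length(dec$cliques)) {
      cl <- dec$cliques[[j]]
      S <- dec$separators[[j - 1]]
      R <- setdiff(cl, S)
      r <- length(R); s <- length(S)
      nu <- delta + length(cl) - 1
      if (s == 0) {
        Sigma[R, R] <- .riw(nu, D[R, R, drop = FALSE])
      } else {
        DSSi <- chol2inv(chol(D[S, S, drop = FALSE]))
        Drs <- D[R, R, drop = FALSE] -
          D[R, S, drop = FALSE] %*% DSSi %*% D[S, R, drop = FALSE]
        Srs <- .riw(nu, Drs)
        M <- D[R, S, drop = FALSE] %*% DSSi
        Z <- matrix(stats::rnorm(r * s), r, s)
        Uu <- M + t(chol(Srs)) %*% Z %*% chol(DSSi)
        ## completion: covariances with all previously placed vertices run
        ## through the separator, which zeroes the precision off the graph
        Sigma[R, done] <- Uu %*% Sigma[S, done, drop = FALSE]
        Sigma[done, R] <- t(Sigma[R, done, drop = FALSE])
        Sigma[R, R] <- Srs +
          Uu %*% Sigma[S, S, drop = FALSE] %*% t(Uu)
      }
      done <- union(done, R)
    }
  }
  Sigma
}
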