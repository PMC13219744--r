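#' Amino-acid substitution model for placement
#'
#' Builds a time-reversible 20-state substitution model from
#' exchangeabilities and equilibrium frequencies, eigen-decomposed once so
#' transition matrices are cheap. `"LG"` uses the Le-Gascuel
#' exchangeabilities and frequencies (taken from phangorn's model tables);
#' `"poisson"` is the equal-rates, equal-frequency model, for which the
#' single-site transition probability has the closed form
#' P(same) = 1/20 + (19/20) exp(-20 t / 19).
#'
#' Rates are normalized so branch lengths are expected substitutions per
#' site. Residues in the standard order ARNDCQEGHILKMFPSTWYV.
#'
#' @param name `"LG"` or `"poisson"`.
#' @return object of class `aa_model` with elements `name`, `pi`, `V`,
#'   `Vinv`, `lambda` (P(t) = V diag(exp(lambda t)) Vinv).
#' @export
substitution_model <- function(name = c("LG", "poisson")) {
  name <- match.arg(name)
  if (name == "LG") {
    lg <- utils::getFromNamespace(".LG", "phangorn")
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- lg$Q
    S <- S + t(S)
    pi <- unname(lg$bf)
  } else {
    S <- matrix(1, 20, 20); diag(S) <- 0
    pi <- rep(1 / 20, 20)
  }
  Q <- S * rep(pi, each = 20)          # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # symmetrize for a stable eigen-decomposition of the reversible generator
  d <- sqrt(pi)
  B <- Q * (d / rep(d, each = 20))     # B_ij = d_i Q_ij / d_j  (symmetric)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- eig$vectors / d                 # rows scaled by 1/d_i
  Vinv <- t(eig$vectors * d)           # columns scaled by d_j, transposed
  structure(list(name = name, pi = pi, V = V, Vinv = Vinv,
                 lambda = eig$values, states = AA20),
            class = "aa_model")
}

#' Transition probability matrix P(t) of an `aa_model`
#' @param model an [substitution_model()] object.
#' @param t branch length (expected substitutions per site), >= 0.
#' @return 20 x 20 matrix, rows = ancestral state.
#' @export
transition_matrix <- function(model, t) {
  P <- model$V %*% (exp(model$lambda * t) * model$Vinv)
  P[P < 0] <- 0
  P
}

# 20 x nsite tip likelihood matrix for a gapped sequence; gaps, X and
# anything outside the 20-letter alphabet are missing data (all ones)
tip_matrix <- function(gapped_seq, model) {
  ch <- strsplit(toupper(gapped_seq), "")[[1]]
  idx <- match(ch, model$states)
  M <- matrix(1, 20, length(ch))
  known <- which(!is.na(idx))
  if (length(known) > 0) {
    M[, known] <- 0
    M[cbind(idx[known], known)] <- 1
  }
  M
}
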