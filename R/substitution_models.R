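# Amino-acid substitution models: the PAM250 similarity matrix (via
# Biostrings) used for searching and distances, and the empirical
# Jones-Taylor-Thornton (JTT, 1992) rate matrix used for likelihood.

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' PAM250 substitution matrix restricted to the 20 standard residues
#'
#' @return A symmetric 20 x 20 integer matrix of log-odds similarity scores.
#' @export
pam250_matrix <- function() {
  m <- get_pam250_full()
  m[AA_ALPHABET20, AA_ALPHABET20]
}

# Full Biostrings PAM250 (includes ambiguity codes), cached.
get_pam250_full <- function() {
  if (is.null(.bhlh_cache$pam250_full)) {
    e <- new.env()
    utils::data("PAM250", package = "Biostrings", envir = e)
    .bhlh_cache$pam250_full <- e$PAM250
  }
  .bhlh_cache$pam250_full
}

.bhlh_cache <- new.env(parent = emptyenv())

# JTT (Jones, Taylor & Thornton 1992) amino-acid exchangeabilities, lower
# triangle filled column-wise in ARNDCQEGHILKMFPSTWYV order, and stationary
# frequencies, as distributed with PAML (jones.dat).
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQ <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' JTT instantaneous rate matrix
#'
#' Builds the reversible JTT rate matrix Q from the published
#' exchangeabilities and stationary frequencies, scaled so that the expected
#' substitution rate at stationarity is one (branch lengths are then in
#' expected substitutions per site).
#'
#' @return List with `Q` (20 x 20 rate matrix), `pi` (stationary
#'   frequencies), both with residues in ARNDCQEGHILKMFPSTWYV order.
#' @export
jtt_rate_matrix <- function() {
  if (!is.null(.bhlh_cache$jtt)) return(.bhlh_cache$jtt)
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  S[lower.tri(S)] <- .JTT_EXCH
  S <- S + t(S)
  pi <- .JTT_FREQ / sum(.JTT_FREQ)
  names(pi) <- AA_ALPHABET20
  Q <- S * rep(pi, each = 20)          # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))          # mean rate 1
  .bhlh_cache$jtt <- list(Q = Q, pi = pi)
  .bhlh_cache$jtt
}

# Eigen machinery for fast transition probabilities of the reversible Q:
# P(t) = U1 %*% (exp(lambda t) * U2), cached once.
jtt_eigen <- function() {
  if (!is.null(.bhlh_cache$jtt_eig)) return(.bhlh_cache$jtt_eig)
  m <- jtt_rate_matrix()
  sp <- sqrt(m$pi)
  B <- m$Q * (sp %o% (1 / sp))         # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  .bhlh_cache$jtt_eig <- list(
    lambda = e$values,
    U1 = e$vectors / sp,               # diag(1/sp) %*% U
    U2 = t(e$vectors * sp),            # t(U) %*% diag(sp)
    pi = m$pi)
  .bhlh_cache$jtt_eig
}

#' JTT transition probability matrix
#'
#' @param t Branch length in expected substitutions per site.
#' @return 20 x 20 matrix of probabilities P(a -> b | t).
#' @export
jtt_prob <- function(t) {
  stopifnot(t >= 0)
  e <- jtt_eigen()
  P <- e$U1 %*% (exp(e$lambda * t) * e$U2)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ALPHABET20, AA_ALPHABET20)
  P
}
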