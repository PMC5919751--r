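# Shared internals: base alphabet, 256-pattern bookkeeping, negativity policy.

BASES <- c("A", "C", "G", "T")

# 256 x 4 matrix of base indices (1..4) for the ordered patterns
# AAAA, AAAC, ..., TTTT (lexicographic, last position varies fastest).
pattern_index_table <- function() {
  k <- 0:255
  cbind(
    a1 = k %/% 64L + 1L,
    a2 = (k %/% 16L) %% 4L + 1L,
    a3 = (k %/% 4L) %% 4L + 1L,
    a4 = k %% 4L + 1L
  )
}

.pattern_tab <- pattern_index_table()

# TRUE where the two alleles form a transition pair {A,G} or {C,T}
is_transition_pair <- function(b1, b2) {
  (pmin(b1, b2) == 1L & pmax(b1, b2) == 3L) |
    (pmin(b1, b2) == 2L & pmax(b1, b2) == 4L)
}

# indices (1..256) of ABBA patterns (x,y,y,x), x != y, and BABA (x,y,x,y)
pattern_abba_idx <- function(drop_transitions = FALSE) {
  t <- .pattern_tab
  keep <- t[, 1] == t[, 4] & t[, 2] == t[, 3] & t[, 1] != t[, 2]
  if (drop_transitions) keep <- keep & !is_transition_pair(t[, 1], t[, 2])
  which(keep)
}

pattern_baba_idx <- function(drop_transitions = FALSE) {
  t <- .pattern_tab
  keep <- t[, 1] == t[, 3] & t[, 2] == t[, 4] & t[, 1] != t[, 2]
  if (drop_transitions) keep <- keep & !is_transition_pair(t[, 1], t[, 2])
  which(keep)
}

#' Clamp negative entries of a (pattern or frequency) vector
#'
#' After an error-matrix or admixture inversion, estimated probability
#' vectors can acquire small negative entries. The default policy clamps
#' them to zero and rescales the vector back to its original total mass;
#' `"strict"` returns the raw values untouched.
#'
#' @param p numeric vector (or matrix, treated row-wise) of masses.
#' @param policy `"clamp"` (default) or `"strict"`.
#' @param warn emit a warning when any entry was clamped?
#' @return vector/matrix of the same shape; attribute `"clamped_mass"`
#'   records the total negative mass removed.
#' @export
apply_negativity_policy <- function(p, policy = c("clamp", "strict"),
                                    warn = FALSE) {
  policy <- match.arg(policy)
  if (policy == "strict") {
    attr(p, "clamped_mass") <- 0
    return(p)
  }
  if (is.matrix(p)) {
    neg <- pmin(p, 0)
    clamped <- -sum(neg)
    if (clamped > 0) {
      tot <- rowSums(p)
      q <- pmax(p, 0)
      qtot <- rowSums(q)
      scale <- ifelse(qtot > 0, tot / qtot, 1)
      p <- q * scale
      if (warn) warning(sprintf("clamped negative mass %.3g", clamped))
    }
    attr(p, "clamped_mass") <- clamped
    return(p)
  }
  neg <- p < 0
  clamped <- -sum(p[neg])
  if (clamped > 0) {
    tot <- sum(p)
    p[neg] <- 0
    s <- sum(p)
    if (s > 0) p <- p * (tot / s)
    if (warn) warning(sprintf("clamped negative mass %.3g", clamped))
  }
  attr(p, "clamped_mass") <- clamped
  p
}

base_index <- function(b) {
  i <- match(b, BASES)
  if (anyNA(i)) stop("unknown base symbol: ", paste(b[is.na(i)], collapse = ","))
  i
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("abbababa_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("abbababa_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
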