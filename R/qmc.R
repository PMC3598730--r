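## Quine-McCluskey two-level minimization.
##
## Implicants are pairs (value, mask): `mask` bits are don't-care
## positions, `value` holds the cared bits.  Bit weights follow the
## context-string convention used everywhere in the package: the FIRST
## input is the most significant bit.

qmCovers <- function(value, mask, m) {
  bitwAnd(m, bitwNot(mask)) == bitwAnd(value, bitwNot(mask))
}

qmPrimeImplicants <- function(terms, nVars) {
  # terms: integer minterms (on-set plus don't-cares)
  cur <- unique(data.frame(value = as.integer(terms), mask = 0L))
  primes <- data.frame(value = integer(0), mask = integer(0))
  while (nrow(cur)) {
    merged <- rep(FALSE, nrow(cur))
    nxt <- data.frame(value = integer(0), mask = integer(0))
    pop <- vapply(seq_len(nrow(cur)), function(i) {
      sum(as.integer(intToBits(bitwAnd(cur$value[i], bitwNot(cur$mask[i])))))
    }, numeric(1))
    for (i in seq_len(nrow(cur))) {
      for (j in seq_len(nrow(cur))) {
        if (i >= j || cur$mask[i] != cur$mask[j] || abs(pop[i] - pop[j]) != 1) next
        d <- bitwXor(cur$value[i], cur$value[j])
        if (bitwAnd(d, d - 1L) == 0L && d != 0L) {
          merged[i] <- merged[j] <- TRUE
          nxt <- rbind(nxt, data.frame(value = bitwAnd(cur$value[i], bitwNot(d)),
                                       mask = bitwOr(cur$mask[i], d)))
        }
      }
    }
    primes <- rbind(primes, cur[!merged, , drop = FALSE])
    cur <- unique(nxt)
  }
  unique(primes)
}

#' Minimize a boolean function (Quine-McCluskey)
#'
#' Computes the prime implicants of the function defined by \code{onSet}
#' (with \code{dcSet} as don't-cares), selects the essential primes and
#' covers the remaining on-set minterms greedily (largest number of newly
#' covered minterms first; ties broken by fewer literals, then by term
#' order), yielding a small sum-of-products equal to the function on all
#' defined assignments.
#'
#' @param onSet integer vector of minterms that must evaluate to 1 (first
#'   variable = most significant bit).
#' @param dcSet integer vector of don't-care minterms.
#' @param nVars number of input variables.
#' @return character vector of product terms over \code{{0,1,-}}, one
#'   character per variable; \code{character(0)} is the constant-0
#'   function, a term of all \code{-} the constant-1 function.
#' @export
minimizeDnf <- function(onSet, dcSet = integer(0), nVars) {
  onSet <- unique(as.integer(onSet))
  dcSet <- setdiff(unique(as.integer(dcSet)), onSet)
  if (!length(onSet)) return(character(0))
  stopifnot(nVars >= 0, all(onSet < 2^nVars), all(dcSet < 2^nVars))
  if (nVars == 0L) return("")  # constant 1

  primes <- qmPrimeImplicants(c(onSet, dcSet), nVars)
  coverMat <- outer(seq_len(nrow(primes)), seq_along(onSet),
                    Vectorize(function(i, j) {
                      qmCovers(primes$value[i], primes$mask[i], onSet[j])
                    }))
  if (!is.matrix(coverMat)) coverMat <- matrix(coverMat, nrow = nrow(primes))

  chosen <- integer(0)
  covered <- rep(FALSE, length(onSet))
  # essential primes
  for (j in seq_along(onSet)) {
    who <- which(coverMat[, j])
    if (length(who) == 1L && !who %in% chosen) {
      chosen <- c(chosen, who)
      covered <- covered | coverMat[who, ]
    }
  }
  # greedy cover of the rest
  nLit <- vapply(seq_len(nrow(primes)), function(i) {
    nVars - sum(as.integer(intToBits(primes$mask[i])))
  }, numeric(1))
  while (!all(covered)) {
    gain <- vapply(seq_len(nrow(primes)), function(i) {
      if (i %in% chosen) -1L else sum(coverMat[i, ] & !covered)
    }, integer(1))
    best <- which(gain == max(gain) & gain > 0L)
    best <- best[order(nLit[best], best)][1]
    chosen <- c(chosen, best)
    covered <- covered | coverMat[best, ]
  }
  chosen <- sort(chosen)
  vapply(chosen, function(i) {
    paste(vapply(seq_len(nVars), function(k) {
      w <- 2^(nVars - k)
      if (bitwAnd(primes$mask[i], w)) "-"
      else if (bitwAnd(primes$value[i], w)) "1" else "0"
    }, character(1)), collapse = "")
  }, character(1))
}

# evaluate a {0,1,-} term list on a minterm
dnfEvalMinterm <- function(terms, m, nVars) {
  if (!length(terms)) return(FALSE)
  for (t in terms) {
    ok <- TRUE
    if (nVars > 0) {
      bits <- strsplit(t, "")[[1]]
      for (k in seq_len(nVars)) {
        if (bits[k] == "-") next
        w <- 2^(nVars - k)
        have <- if (bitwAnd(m, w)) "1" else "0"
        if (have != bits[k]) { ok <- FALSE; break }
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}
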