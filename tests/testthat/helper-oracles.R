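# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force rather than calling the package's own code paths.

# Exact expected vacancy count of dimer RSA at jamming, by full enumeration
# of the uniform-over-feasible-bonds decision tree. Exponential; fine for
# small n only.
brute_force_vacancies <- function(n) {
  rec <- function(occ) {
    free <- which(!occ[-length(occ)] & !occ[-1])
    if (length(free) == 0) {
      return(sum(!occ))
    }
    vals <- vapply(free, function(b) {
      o2 <- occ
      o2[b] <- TRUE
      o2[b + 1] <- TRUE
      rec(o2)
    }, numeric(1))
    mean(vals)
  }
  rec(logical(n))
}

# Maximal TRUE-runs of a logical vector by a naive position scan
# (independent of the package's rle-based implementation).
naive_runs <- function(bits) {
  out <- list()
  i <- 1
  while (i <= length(bits)) {
    if (bits[i]) {
      j <- i
      while (j <= length(bits) && bits[j]) j <- j + 1
      out[[length(out) + 1]] <- c(start = i - 1L, end = j - 1L)
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Random base string helper for property tests.
random_bases <- function(n, p_at = 0.5) {
  classes <- runif(n) < p_at
  chars <- ifelse(classes,
                  sample(c("A", "T"), n, replace = TRUE),
                  sample(c("G", "C"), n, replace = TRUE))
  paste(chars, collapse = "")
}
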