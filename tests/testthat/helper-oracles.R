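# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, exhaustive enumeration, direct
# formula sums.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# adjust flank boundary bases so they cannot extend a planted repeat array
safe_flanks <- function(left, right, unit) {
  bases <- c("A", "C", "G", "T")
  last_u <- substr(unit, nchar(unit), nchar(unit))
  first_u <- substr(unit, 1, 1)
  substr(left, nchar(left), nchar(left)) <- setdiff(bases, last_u)[1]
  substr(right, 1, 1) <- setdiff(bases, first_u)[1]
  list(left = left, right = right)
}

# primitive 2-4 bp unit check, by direct division
oracle_primitive <- function(u) {
  n <- nchar(u)
  if (n < 2 || n > 4 || grepl("[^ACGT]", u)) return(FALSE)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 && u == strrep(substr(u, 1, d), n / d)) return(FALSE)
  }
  TRUE
}

# brute-force STR scan: test every (start, unit length), extend base by
# base, keep maximal whole-unit arrays, then resolve overlaps by the
# longest / leftmost / shortest-unit rule
oracle_scan <- function(seq, min_units) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  cand <- list()
  for (u in 2:4) {
    for (i in seq_len(max(0, n - 2 * u + 1))) {
      unit <- substr(seq, i, i + u - 1)
      if (!oracle_primitive(unit)) next
      # maximality on the left: previous base must not continue the array
      if (i > 1 && valid[i - 1] && ch[i - 1] == ch[i - 1 + u]) next
      j <- i
      while (j + u <= n && valid[j] && valid[j + u] && ch[j] == ch[j + u]) {
        j <- j + 1
      }
      span <- (j - i) + u
      count <- span %/% u
      if (count >= min_units) {
        cand[[length(cand) + 1]] <-
          data.frame(start = i - 1, end = i - 1 + span,
                     unit = unit, unit_count = count,
                     len = span, ulen = u)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), unit_count = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$start, cand$ulen), ]
  covered <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    span <- (cand$start[k] + 1):cand$end[k]
    if (!any(covered[span])) {
      covered[span] <- TRUE
      keep[k] <- TRUE
    }
  }
  out <- cand[keep, c("start", "end", "unit", "unit_count")]
  out[order(out$start), ]
}

# PID by exhaustive genotype enumeration: sum over unordered genotypes of
# the squared Hardy-Weinberg probability
oracle_pid <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in 1:k) {
    for (j in i:k) {
      pr <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      tot <- tot + pr^2
    }
  }
  tot
}

# PID(sib) by exhaustive parental-genotype and transmission enumeration:
# two parents with HW genotypes, two children each receiving one random
# allele from each parent; probability both children share the same
# unordered genotype
oracle_pid_sib <- function(p) {
  k <- length(p)
  tot <- 0
  for (f1 in 1:k) for (f2 in 1:k) for (m1 in 1:k) for (m2 in 1:k) {
    pr_parents <- p[f1] * p[f2] * p[m1] * p[m2]
    f <- c(f1, f2); m <- c(m1, m2)
    # transmission: 4 equally likely gametes per child
    same <- 0
    for (a1 in 1:2) for (b1 in 1:2) for (a2 in 1:2) for (b2 in 1:2) {
      g1 <- sort(c(f[a1], m[b1]))
      g2 <- sort(c(f[a2], m[b2]))
      if (all(g1 == g2)) same <- same + 1
    }
    tot <- tot + pr_parents * same / 16
  }
  tot
}

# independent primer-pair constraint checker (plain string ops, rle runs)
oracle_primer_pair_ok <- function(fwd, rev, product_sizes,
                                  max_amplicon = 150) {
  one <- function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    gc <- sum(ch %in% c("G", "C")) / length(ch)
    tm <- 2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
    runs <- rle(ch)
    last5 <- ch[(length(ch) - 4):length(ch)]
    length(ch) >= 18 && length(ch) <= 22 &&
      gc >= 0.40 && gc <= 0.60 &&
      tm >= 54 && tm <= 62 &&
      max(runs$lengths) <= 4 &&
      ch[length(ch)] %in% c("G", "C") &&
      sum(last5 %in% c("G", "C")) <= 3
  }
  tmf <- 2 * lengths(regmatches(fwd, gregexpr("[AT]", fwd))) +
    4 * lengths(regmatches(fwd, gregexpr("[GC]", fwd)))
  tmr <- 2 * lengths(regmatches(rev, gregexpr("[AT]", rev))) +
    4 * lengths(regmatches(rev, gregexpr("[GC]", rev)))
  one(fwd) && one(rev) &&
    nchar(fwd) + nchar(rev) >= 36 && nchar(fwd) + nchar(rev) <= 44 &&
    abs(tmf - tmr) <= 3 &&
    max(product_sizes) <= max_amplicon
}

# naive in-silico PCR: all-pairs site combination with plain R loops
oracle_amplify <- function(fwd, rev, tpl, max_mismatch, three_prime_exact,
                           max_product) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  sites <- function(primer, template, anchor) {
    m <- nchar(primer); n <- nchar(template)
    pc <- strsplit(primer, "", fixed = TRUE)[[1]]
    tc <- strsplit(template, "", fixed = TRUE)[[1]]
    anchor_idx <- if (anchor == "end") (m - three_prime_exact + 1):m
                  else 1:three_prime_exact
    hit <- integer()
    for (s in 0:(n - m)) {
      win <- tc[(s + 1):(s + m)]
      ok_pos <- pc == win & pc %in% c("A", "C", "G", "T")
      if (all(ok_pos[anchor_idx]) && sum(!ok_pos) <= max_mismatch) {
        hit <- c(hit, s)
      }
    }
    hit
  }
  plus <- c(sites(fwd, tpl, "end"), sites(rev, tpl, "end"))
  minus_f <- sites(rc(fwd), tpl, "start")
  minus_r <- sites(rc(rev), tpl, "start")
  minus_end <- c(minus_f + nchar(fwd), minus_r + nchar(rev))
  lens <- integer()
  for (s in plus) {
    for (e in minus_end) {
      l <- e - s
      if (l > 0 && l <= max_product) lens <- c(lens, l)
    }
  }
  sort(lens)
}
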