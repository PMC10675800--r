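# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates hypergeometric
# probabilities from binomial coefficients, and the Ward oracle recomputes
# merge costs from raw coordinates via the explicit ESS-increase formula.

# Two-sided Fisher exact p by direct enumeration with choose().
fisher_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Ward merge cost between two clusters of raw points:
# delta ESS = |A||B|/(|A|+|B|) * ||centroid_A - centroid_B||^2
ward_merge_cost <- function(x, idx_a, idx_b) {
  ca <- colMeans(x[idx_a, , drop = FALSE])
  cb <- colMeans(x[idx_b, , drop = FALSE])
  na <- length(idx_a); nb <- length(idx_b)
  na * nb / (na + nb) * sum((ca - cb)^2)
}

# Replay a ward_clust merge sequence on the raw matrix and check that every
# step merged a pair of minimal Ward cost (exhaustive over current pairs).
# Returns the largest violation (chosen cost minus minimal cost).
ward_stepwise_gap <- function(x, tree) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))        # leaf clusters
  worst <- 0
  for (s in seq_len(n - 1)) {
    act <- which(!vapply(clusters, is.null, logical(1)))
    costs <- c()
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in (ii + 1):length(act)) {
        costs <- c(costs, ward_merge_cost(x, clusters[[act[ii]]],
                                          clusters[[act[jj]]]))
      }
    }
    left <- tree$merge[s, 1]; right <- tree$merge[s, 2]
    child_members <- function(e) {
      if (e < 0) return(-e)
      c(child_members(tree$merge[e, 1]), child_members(tree$merge[e, 2]))
    }
    ma <- child_members(left); mb <- child_members(right)
    chosen <- ward_merge_cost(x, ma, mb)
    worst <- max(worst, chosen - min(costs))
    # apply the merge: the new cluster replaces both
    slot_a <- which(vapply(clusters, function(cl)
      !is.null(cl) && all(ma %in% cl) && length(cl) == length(ma),
      logical(1)))[1]
    slot_b <- which(vapply(clusters, function(cl)
      !is.null(cl) && all(mb %in% cl) && length(cl) == length(mb),
      logical(1)))[1]
    clusters[[slot_a]] <- c(ma, mb)
    clusters[slot_b] <- list(NULL)
  }
  worst
}

# Adjusted Rand index between two labelings (chance-corrected agreement).
ari <- function(x, y) {
  mclust::adjustedRandIndex(x, y)
}

# Minimal in-memory FAERS fixture: three cases, one duplicated version,
# mixed roles, one orphan reaction row.
tiny_faers_tables <- function() {
  demo <- tibble::tibble(
    primaryid = c("71", "72", "81", "91"),
    caseid    = c("7",  "7",  "8",  "9"),
    age = c("60", "61", "45", "30"), sex = c("F", "F", "M", "F")
  )
  drug <- tibble::tibble(
    primaryid = c("71", "72", "72", "81", "81", "91"),
    caseid    = c("7",  "7",  "7",  "8",  "8",  "9"),
    role_cod  = c("PS", "PS", "C",  "PS", "SS", "C"),
    drugname  = c("MORPHINE SULFATE", "MORPHINE SULFATE", "ASPIRIN",
                  "Fentanyl Citrate", "MORPHINE SULFATE", "IBUPROFEN")
  )
  reac <- tibble::tibble(
    primaryid = c("72", "72", "81", "91", "999"),
    caseid    = c("7",  "7",  "8",  "9",  "99"),
    pt = c("NAUSEA", "SOMNOLENCE", "NAUSEA", "RASH", "NAUSEA")
  )
  indi <- tibble::tibble(
    primaryid = c("72"), caseid = c("7"),
    indi_pt = c("PAIN")
  )
  list(demo = demo, drug = drug, reac = reac, indi = indi)
}

# Ten-report membership fixture from the contingency examples:
# 4 reports with the drug, 3 of those with the event, 2 non-drug reports
# with the event.
ten_report_pairs <- function() {
  ids <- sprintf("r%02d", 1:10)
  list(
    drug_pairs = tibble::tibble(caseid = ids[1:4], drug = "drugx"),
    event_pairs = tibble::tibble(caseid = c(ids[1:3], ids[5:6]),
                                 pt = "EVENTX"),
    n_reports = 10
  )
}

# Write a "$"-delimited file from a header and body lines.
write_dollar_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
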