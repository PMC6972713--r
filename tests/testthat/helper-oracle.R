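# Independent brute-force subset scorer: plain loops, no shared code with
# classify_record() beyond the profile data. Scores a level vector against
# every profile, picks the max, breaks ties by total ordinal distance to the
# nearest admissible levels, then by the fixed priority.
oracle_classify <- function(levels, profiles,
                            priority = c("CAF-S1", "CAF-S4", "CAF-S3", "CAF-S2")) {
  markers <- names(profiles[[1]])
  score <- numeric(0)
  dist <- numeric(0)
  for (s in names(profiles)) {
    sc <- 0
    dd <- 0
    for (m in markers) {
      adm <- profiles[[s]][[m]]
      if (levels[[m]] %in% adm) sc <- sc + 1
      dd <- dd + min(abs(levels[[m]] - adm))
    }
    score[s] <- sc
    dist[s] <- dd
  }
  cand <- names(score)[score == max(score)]
  if (length(cand) > 1) {
    cand <- cand[dist[cand] == min(dist[cand])]
    cand <- cand[order(match(cand, priority))]
  }
  cand[1]
}

# All level vectors over a panel (rows of a data frame).
all_level_vectors <- function(markers, levels = 0:3) {
  g <- do.call(expand.grid, stats::setNames(rep(list(levels), length(markers)),
                                            markers))
  as.matrix(g)
}

# Tiles whose 8-neighbourhood shares their label (region interiors).
interior_tiles <- function(truth) {
  ok <- matrix(TRUE, nrow(truth), ncol(truth))
  for (dr in -1:1) {
    for (dc in -1:1) {
      r <- pmin(pmax(row(truth) + dr, 1), nrow(truth))
      c <- pmin(pmax(col(truth) + dc, 1), ncol(truth))
      ok <- ok & (matrix(truth[cbind(as.vector(r), as.vector(c))],
                         nrow(truth)) == truth)
    }
  }
  ok
}

digest_file <- function(path) unname(tools::md5sum(path))

rel_l2 <- function(a, b) {
  sqrt(sum((a$vx - b$vx)^2 + (a$vy - b$vy)^2) / sum(b$vx^2 + b$vy^2))
}
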