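# Independent oracles and shared fixtures for the test suite. Every oracle
# here is written against the definitions directly (enumeration, pair
# counting, step-by-step arithmetic) and never calls the code path it
# checks.

# --- brute-force global alignment score: enumerate every alignment -------
# recursion over the three column types, accumulating the column scores;
# no DP table, no traceback, so ties and ordering cannot leak in
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# --- Mann-Whitney AUC: concordant + half-tied pairs over all pos/neg ----
mann_whitney_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# --- step-by-step TOPSIS (classical variant), scalar loops throughout ---
topsis_by_hand <- function(X, directions, weights) {
  m <- nrow(X); n <- ncol(X)
  R <- matrix(0, m, n)
  for (j in 1:n) {
    nrm <- sqrt(sum(X[, j]^2))
    for (i in 1:m) R[i, j] <- X[i, j] / nrm
  }
  V <- matrix(0, m, n)
  for (j in 1:n) for (i in 1:m) V[i, j] <- weights[j] * R[i, j]
  ideal <- numeric(n); anti <- numeric(n)
  for (j in 1:n) {
    if (directions[j] == "benefit") {
      ideal[j] <- max(V[, j]); anti[j] <- min(V[, j])
    } else {
      ideal[j] <- min(V[, j]); anti[j] <- max(V[, j])
    }
  }
  cl <- numeric(m)
  for (i in 1:m) {
    sp <- sqrt(sum((V[i, ] - ideal)^2))
    sm <- sqrt(sum((V[i, ] - anti)^2))
    cl[i] <- sm / (sp + sm)
  }
  cl
}

# --- small fixtures ------------------------------------------------------
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

tiny_dataset <- function() {
  g <- tibble::tibble(
    guide_id = c("g1", "g2"),
    sequence = c("GATTACAGATTACAGATTAC", "ACGTACGTACGTACGTAC"),
    crop = c("rice", "wheat"))
  mk_site <- function(id, gid, proto, pam, label) {
    ctx <- paste0(strrep("A", 10), proto, pam, strrep("C", 10))
    tibble::tibble(site_id = id, guide_id = gid, protospacer = proto,
                   pam = pam, context = ctx, context_offset = 10L,
                   label = label, strand = "+", source = "fixture")
  }
  s <- dplyr::bind_rows(
    mk_site("s1", "g1", "GATTACAGATTACAGATTAC", "TGG", 1L),
    mk_site("s2", "g1", "GATTACAGATTACAGATTAA", "AAG", 0L),
    mk_site("s3", "g2", "ACGTACGTACGTACGTAC", "CGG", 1L),
    mk_site("s4", "g2", "ACGTACGTACCTACGTAC", "CAG", 0L))
  guide_dataset(g, s)
}

# featurized default synthetic dataset, computed once per test run
shared_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(seed = 104L)
      ds <- split_dataset(ds, 0.7, seed = 105L)
      f <- featurize_dataset(ds)
      f$split <- ds$sites$split[match(f$site_id, ds$sites$site_id)]
      cache <<- f
    }
    cache
  }
})
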