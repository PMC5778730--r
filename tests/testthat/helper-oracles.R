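# Independent brute-force oracles: explicit enumeration, kept free of the
# package's own vectorised implementations.

brute_auroc <- function(risks, outcomes) {
  e <- risks[outcomes == 1]
  ne <- risks[outcomes == 0]
  s <- 0
  for (x in e) {
    for (y in ne) {
      s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  s / (length(e) * length(ne))
}

# Per-subject category by explicit counting of cutpoints at or below the risk
brute_category <- function(risk, cutpoints) {
  sum(risk >= cutpoints) + 1L
}

# Per-subject scoring rule: events +1 up / -1 down, non-events mirrored
brute_nri <- function(old, new, outcomes, cutpoints,
                      method = c("stratified", "unstratified")) {
  method <- match.arg(method)
  score <- numeric(length(old))
  for (i in seq_along(old)) {
    oc <- brute_category(old[i], cutpoints)
    nc <- brute_category(new[i], cutpoints)
    s <- if (nc > oc) 1 else if (nc < oc) -1 else 0
    score[i] <- if (outcomes[i] == 1) s else -s
  }
  if (method == "unstratified") {
    sum(score) / length(score)
  } else {
    sum(score[outcomes == 1]) / sum(outcomes == 1) +
      sum(score[outcomes == 0]) / sum(outcomes == 0)
  }
}

# Small random cohort with both outcome classes guaranteed
make_toy_cohort <- function(n, seed) {
  set.seed(seed)
  risk <- runif(n)
  outcome <- rbinom(n, 1L, 0.4)
  if (sum(outcome) == 0L) outcome[1L] <- 1L
  if (sum(outcome) == n) outcome[1L] <- 0L
  data.frame(subject_id = seq_len(n), risk = risk, outcome = outcome)
}
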