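# Independent brute-force enumeration oracle for the pragmatic listener.
#
# Deliberately shares no code with the package: plain linear-space
# arithmetic, explicit loops over worlds/utterances, and the observation law
# obtained by enumerating every concrete subset of objects with utils::combn
# rather than a hypergeometric density. Used only as a reference in tests.

oracle_meanings <- function(N, with_numerals) {
  m <- list(none = 0L, some = seq_len(N), all = N)
  if (with_numerals) {
    for (k in seq_len(N)) m[[paste0("num", k)]] <- k:N
  }
  m
}

# P(observe o property-bearing objects | world w) by subset enumeration:
# objects 1..w have the property; every size-`access` subset is equally likely
oracle_obs_prob <- function(N, w, access, o) {
  subsets <- utils::combn(N, access)
  hits <- 0
  for (j in seq_len(ncol(subsets))) {
    if (sum(subsets[, j] <= w) == o) hits <- hits + 1
  }
  hits / ncol(subsets)
}

# unnormalized L1 score for one alternative set; returns vector over 0..N
oracle_scores <- function(N, access, alpha, with_numerals, prior, utt = "some") {
  meanings <- oracle_meanings(N, with_numerals)
  labels <- names(meanings)
  # literal listener per utterance: vector over worlds 0..N
  l0 <- list()
  for (u in labels) {
    raw <- numeric(N + 1)
    for (w in 0:N) raw[w + 1] <- if (w %in% meanings[[u]]) prior[w + 1] else 0
    l0[[u]] <- if (sum(raw) > 0) raw / sum(raw) else raw
  }
  score <- numeric(N + 1)
  for (w in 0:N) {
    for (o in 0:access) {
      p_obs <- oracle_obs_prob(N, w, access, o)
      if (p_obs == 0) next
      # speaker belief over all worlds given (access, o)
      belief <- numeric(N + 1)
      for (v in 0:N) belief[v + 1] <- prior[v + 1] * oracle_obs_prob(N, v, access, o)
      belief <- belief / sum(belief)
      # softmax weights in linear space: prod_v L0(v|u)^(alpha * belief(v))
      weight <- numeric(length(labels))
      names(weight) <- labels
      for (u in labels) {
        wgt <- 1
        for (v in 0:N) {
          if (belief[v + 1] > 0) {
            lv <- l0[[u]][v + 1]
            if (lv == 0) {
              wgt <- 0
              break
            }
            wgt <- wgt * lv^(alpha * belief[v + 1])
          }
        }
        weight[u] <- wgt
      }
      if (sum(weight) == 0) next # mute state: contributes nothing
      s1 <- weight[utt] / sum(weight)
      score[w + 1] <- score[w + 1] + prior[w + 1] * p_obs * s1
    }
  }
  score
}

# full pragmatic listener with alternative-set mixture, normalized
oracle_L1 <- function(N, access, alpha, p_with_numerals, prior, utt = "some") {
  s <- (1 - p_with_numerals) * oracle_scores(N, access, alpha, FALSE, prior, utt) +
    p_with_numerals * oracle_scores(N, access, alpha, TRUE, prior, utt)
  s / sum(s)
}
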