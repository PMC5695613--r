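# Small networks with known closed-form behaviour, built fresh for each
# test run.

birthDeathModel <- function(kSyn = 0.01, kDeg = 1e-4, x0 = 10) {
  buildModel("birth_death",
    rbind(speciesSpec("A", x0)),
    list(reactionSpec(character(0), "A", "k_syn"),
         reactionSpec("A", character(0), "k_deg")),
    c(k_syn = kSyn, k_deg = kDeg))
}

pureDeathModel <- function(kDeg = 1e-3, x0 = 100) {
  buildModel("pure_death",
    rbind(speciesSpec("A", x0)),
    list(reactionSpec("A", character(0), "k_deg")),
    c(k_deg = kDeg))
}

conversionModel <- function(a0 = 300, b0 = 200) {
  buildModel("conversion",
    rbind(speciesSpec("A", a0), speciesSpec("B", b0)),
    list(reactionSpec("A", "B", "k_ab"),
         reactionSpec("B", "A", "k_ba")),
    c(k_ab = 2e-4, k_ba = 1e-4))
}

# multiply all copy numbers by `factor` and divide bimolecular rate
# constants by it, preserving the deterministic mean-field equations
scaleModelCounts <- function(model, factor) {
  sp <- model@species
  sp$initial <- sp$initial * factor
  rates <- model@rates
  for (rx in model@reactions)
    if (length(rx$reactants) == 2L)
      rates[rx$rate] <- model@rates[[rx$rate]] / factor
  buildModel(model@name, sp, model@reactions, rates, model@notes)
}

# direct step-up implementation used as the multiple-testing oracle
bhDirect <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive-enumeration oracle for the hypergeometric tail: probability
# that a uniformly random n-subset of {1..N} containing K marked elements
# has at least k marked elements
enumTailP <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}
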