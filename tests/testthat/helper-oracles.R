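# Independent brute-force oracles, deliberately coded as plain loops that
# share no internals with the package's vectorized distance path.

# conditional class probability by direct counting
brute_cond_prob <- function(base, attr, value, cls, alpha) {
  v <- base$x[[attr]]; y <- base$y
  Y <- base$class_values
  n_v <- 0; n_va <- 0
  for (i in seq_along(v)) {
    if (!is.na(v[i]) && v[i] == value && !is.na(y[i])) {
      n_v <- n_v + 1
      if (y[i] == cls) n_va <- n_va + 1
    }
  }
  if (n_v + alpha * length(Y) == 0) return(1 / length(Y))
  (n_va + alpha) / (n_v + alpha * length(Y))
}

brute_vdm <- function(base, attr, vt, vr, alpha, variant) {
  if (is.na(vt) || is.na(vr)) return(1)
  if (vt == vr) return(0)
  Y <- base$class_values
  s <- 0; f <- 0
  for (a in Y) {
    pt <- brute_cond_prob(base, attr, vt, a, alpha)
    pr <- brute_cond_prob(base, attr, vr, a, alpha)
    s <- s + (pt - pr)^2
    f <- f + pt^2
  }
  if (variant == "as_printed") s * f else s
}

# WHVDM(t, r) computed attribute by attribute from the raw definition;
# assumes continuous attributes already normalized
brute_whvdm <- function(t_x, r_x, w, base, alpha = 1,
                       variant = "as_printed", missing_penalty = 1) {
  total <- 0
  for (j in seq_len(nrow(base$schema))) {
    nm <- base$schema$name[j]
    vt <- t_x[[nm]]; vr <- r_x[[nm]]
    d <- if (base$schema$kind[j] == "continuous") {
      if (is.na(vt) || is.na(vr)) missing_penalty else (vt - vr)^2
    } else {
      brute_vdm(base, nm, vt, vr, alpha, variant)
    }
    total <- total + w[j] * d
  }
  total
}

# the 6-case toy base behind the hand-enumerated VDM values:
# value a seen with classes pos,pos,neg,neg -> Pr(pos|a) = 0.5
# value b seen with classes pos,pos         -> Pr(pos|b) = 1.0
toy_vdm_base <- function() {
  case_base(data.frame(attr = c("a", "a", "a", "a", "b", "b")),
            y = c("pos", "pos", "neg", "neg", "pos", "pos"))
}

# small labeled corpus for ensemble tests
tiny_corpus <- function(q = 1, n_docs = 3, M = 3, N = 3, seed = 1) {
  gen_emr_corpus(corpus_gen_spec(n_docs = n_docs, classifier_fidelity = q,
                                 M = M, N = N, seed = seed))
}
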