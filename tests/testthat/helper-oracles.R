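# Independent oracles used across the suite. These deliberately avoid the
# package's own construction/inference code paths: kernels are recomputed
# from the definition, posteriors by exhaustive enumeration of the joint.

FLOOR <- 1e-16

flog_ <- function(p) log(pmax(p, FLOOR))

# squared-exponential kernel on an index grid, truncated and renormalized
kernel_oracle <- function(n, mode_index, precision, idx = seq_len(n)) {
  w <- exp(-precision * (idx - idx[mode_index])^2 / 2)
  w / sum(w)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# exhaustive-enumeration posterior for a single trial with <= 2 epochs:
# joint over (s3, s1 trajectory, s2 trajectory) under the floored-log model,
# matching the effective model used by the mean-field engine
enumerate_posterior <- function(model, priors, obs) {
  n1 <- model$space$n_internal
  n2 <- model$space$n_external
  n3 <- nrow(priors$disp)
  T_ <- obs$n_epochs
  stopifnot(T_ <= 2)
  lD <- flog_(priors$disp)
  lS <- flog_(priors$sit)
  lP <- flog_(priors$person)
  lB1 <- flog_(model$B1)
  lB2 <- flog_(model$B2)
  lobs1 <- function(t, i, k) {
    if (is.na(obs$o1[t])) 0 else flog_(model$A1[obs$o1[t], i, k])
  }
  lobs2 <- function(t, k) {
    if (is.na(obs$o2[t])) 0 else flog_(model$A2[obs$o2[t], k])
  }
  states <- expand.grid(
    s3 = seq_len(n3),
    s1a = seq_len(n1), s2a = seq_len(n2),
    s1b = if (T_ == 2) seq_len(n1) else 1L,
    s2b = if (T_ == 2) seq_len(n2) else 1L)
  lj <- with(states, {
    v <- lP[s3] + lD[cbind(s3, s1a)] + lS[cbind(s3, s2a)] +
      lobs2(1, s2a) + mapply(lobs1, 1, s1a, s2a)
    if (T_ == 2)
      v <- v + lB1[cbind(s1b, s1a)] + lB2[cbind(s2b, s2a)] +
        lobs2(2, s2b) + mapply(lobs1, 2, s1b, s2b)
    v
  })
  w <- exp(lj - max(lj))
  p <- w / sum(w)
  marg <- function(f) as.numeric(tapply(p, states[[f]], sum))
  out <- list(
    q_person = marg("s3"),
    q1 = cbind(marg("s1a"), if (T_ == 2) marg("s1b")),
    q2 = cbind(marg("s2a"), if (T_ == 2) marg("s2b")),
    log_evidence = log(sum(w)) + max(lj))
  out
}

# truncated-normal lower-tail mass by numeric quadrature
truncnorm_cdf_oracle <- function(q, mean, sd) {
  dens <- function(x) dnorm(x, mean, sd)
  Z <- integrate(dens, 0, 1, rel.tol = 1e-10)$value
  integrate(dens, 0, min(q, 1), rel.tol = 1e-10)$value / Z
}

# small helper: default simulation-mode model at given parameters
sim_model <- function(...) split_hmm(split_params(...))
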