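# Shared fixtures: parameter sets built in code, small estimation budgets.

gen_params <- function(...) deb_params(...)

abj_params <- function(EHj_mult = 10, ...) {
  deb_params(E_Hj = 0.275 * EHj_mult, ...)
}

# deterministically perturb the free parameters of a set
perturb_params <- function(p, free, amount = 0.2, seed = 42) {
  set.seed(seed)
  for (nm in free) p[[nm]] <- p[[nm]] * runif(1, 1 - amount, 1 + amount)
  attr(p, "free") <- free
  p
}

quick_options <- function(steps = 100, continuations = 1, ...) {
  estimation_options(steps = steps, continuations = continuations, ...)
}

# states at requested ages, by exact match against requested output times
states_at <- function(traj, ages) {
  idx <- vapply(ages, function(a) which.min(abs(traj$t - a)), integer(1))
  traj[idx, , drop = FALSE]
}
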