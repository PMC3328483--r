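# Internal helpers shared across modules.

# Structured error: every condition carries a package-specific class so
# callers (and tests) can dispatch on failure kind rather than message text.
stop_adx <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "admixscan_error"),
                      call = call))
}

warn_adx <- function(message, class) {
  warning(warningCondition(message, class = c(class, "admixscan_warning")))
}

# log10 of a sum of 10^x terms without overflow; x may span hundreds of
# LOD units when summing per-case likelihood ratios.
log10_sum <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

log10_mean <- function(x) log10_sum(x) - log10(length(x))

# Allele frequencies are clamped away from 0/1 before entering any
# likelihood: a fixed difference marker plus a conflicting genotype must
# never yield a zero-probability observation.
FREQ_EPS <- 1e-4
clamp_freq <- function(f) pmin(pmax(f, FREQ_EPS), 1 - FREQ_EPS)

# Hardy-Weinberg prior over Native-copy counts (0,1,2) given theta.
hwe_prior <- function(theta) {
  cbind((1 - theta)^2, 2 * theta * (1 - theta), theta^2)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
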