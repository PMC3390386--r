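# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All seeded operations in the package
# route through this so that generation is reproducible without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream of child seeds from one parent seed, below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nS * mV across a membrane of `area` cm^2, expressed as uA/cm^2.
# 1 nS * 1 mV = 1 pA; 1 pA / cm^2 = 1e-6 uA/cm^2.
NS_MV_TO_UA_PER_CM2 <- 1e-6

# Conductance density (mS/cm^2) over `area` cm^2 -> absolute nS.
# 1 mS = 1e6 nS.
density_to_ns <- function(g_density, area) g_density * area * 1e6

# Absolute conductance nS -> input resistance MOhm (1/nS = GOhm = 1e3 MOhm).
ns_to_mohm <- function(g_ns) 1000 / g_ns

package_env <- new.env(parent = emptyenv())
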