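# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls do not perturb user scripts.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number")
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    expr
}

.assertScalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("invalid '", name, "': must be a single finite number",
             call. = FALSE)
    if (x < min || x > max)
        stop("invalid '", name, "': must be in [", min, ", ", max, "]",
             call. = FALSE)
    if (integer && x != round(x))
        stop("invalid '", name, "': must be a whole number", call. = FALSE)
    invisible(TRUE)
}

.pct <- function(num, den) 100 * num / den
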