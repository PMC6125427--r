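# Internal helpers shared across modules.

# Derive an independent per-stage RNG seed from one global seed.  Stages are
# named so that adding a stage never perturbs another stage's stream.  The
# result stays below 2^31 - 1.
deriveSeed <- function(seed, stage) {
    stopifnot(length(seed) == 1L, is.finite(seed))
    offs <- c(truth = 101L, baseline = 211L, noise = 307L,
              direction = 401L, effect = 503L, annotation = 601L)
    if (!stage %in% names(offs))
        stop("unknown RNG stage: ", stage)
    (abs(as.integer(seed)) %% 1000003L) * 1009L + offs[[stage]]
}

# Map a user-supplied group identifier (slug or display name) to the slug.
resolveGroup <- function(design, group) {
    g <- design@groups
    if (group %in% g$group) return(group)
    hit <- match(group, g$displayName)
    if (!is.na(hit)) return(g$group[hit])
    stop("unknown group '", group, "' for platform ", design@platform,
         " (known: ", paste(g$group, collapse = ", "), ")")
}

# Strict full-precision TSV writer for numeric matrices (17 significant
# digits survives a double round trip).
formatFull <- function(x) {
    vapply(x, function(v) sprintf("%.17g", v), character(1))
}

stopIfNotSameUniverse <- function(a, b, what = "inputs") {
    if (!identical(sort(a), sort(b)))
        stop(what, " are defined over different transcript universes")
}
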