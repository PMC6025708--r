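# shared fixtures built in code

grid_2cyc <- function(interval) seq(0, 48 - interval, by = interval)

# a random strictly monotone map, for invariance checks
random_monotone <- function(rng_id) {
    switch((rng_id %% 4) + 1,
           function(v) exp(v),
           function(v) v^3 + 2 * v,
           function(v) atan(v) * 5 - 1,
           function(v) rank(v, ties.method = "first") / length(v))
}

# independent MCC evaluation, written out term by term
mcc_by_hand <- function(tp, fp, tn, fn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / den
}
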