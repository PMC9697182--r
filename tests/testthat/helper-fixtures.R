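# Shared fixtures. The demo cohort (n = 100 children, fixed seed, test
# backbone) with its produced-only fc7 features is expensive, so it is built
# once per test run and memoized.

make_agent <- function(style, alpha = 1, age = 60, motif_seed = 7L,
                       child_id = "cX") {
  w <- stats::setNames(as.numeric(drawrsa:::DRAW_STYLES == style),
                       drawrsa:::DRAW_STYLES)
  structure(
    list(
      child_id = child_id, age_months = as.integer(age), alpha = alpha,
      style_weights = w, motif_seed = motif_seed, aq_propensity = 0.3
    ),
    class = "child_agent"
  )
}

zero_jitter_params <- function() cohort_params(stroke_jitter_sd = 0)

demo_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bundle <- simulate_cohort(100, seed = 1)
      backbone <- make_test_backbone(1001)
      kid_feats <- compute_drawing_features(bundle$drawings, backbone,
        layers = "fc7", produced_only = TRUE
      )
      adult_feats <- compute_drawing_features(bundle$adult_drawings, backbone,
        layers = "fc7", produced_only = TRUE
      )
      cache <<- list(
        bundle = bundle, backbone = backbone,
        kid_feats = kid_feats, adult_feats = adult_feats
      )
    }
    cache
  }
})

# Brute-force Pearson distance oracle (independent of the implementation).
oracle_distance <- function(x, y) 1 - stats::cor(x, y)
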