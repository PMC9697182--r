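# Shared vocabulary of the task design.

DRAW_CATEGORIES <- c("face", "house", "car", "human")
DRAW_CONDITIONS <- c("outline", "inner", "scrambled")
DRAW_STYLES <- c("none", "scribble", "trace", "color", "complete", "off_target")
RATED_STYLES <- c("completion", "scribbling", "tracing", "coloring")
GUESS_OPTIONS <- c(DRAW_CATEGORIES, "dont_know")

# Seven analysis layers of a VGG-style backbone, ordered local -> global.
ANALYSIS_LAYERS <- c(paste0("pool", 1:5), "fc6", "fc7")
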