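#' Simulate a labelled two-group cohort over a synthetic stimulus
#'
#' End-to-end convenience for studies without clinical data: renders the
#' stimulus, preprocesses it, generates one gaze stream per synthetic
#' subject from the group-conditional phenotype parameters, and maps every
#' stream into the working frame grid.  Subject streams are deterministic
#' given `seed` (subject `i` of a group uses a seed derived from it).
#'
#' @param manifest a [scene_manifest()].
#' @param n_per_group subjects per group.
#' @param params_case,params_control [phenotype_params()] of the two
#'   groups; the defaults encode a case group preferring geometric motion
#'   (`p_geometric = 0.8`) and a control group preferring biological
#'   motion (`p_geometric = 0.2`).
#' @param sampling_rate tracker rate in Hz.
#' @param seed integer master seed.
#' @param dim,n_trim preprocessing settings (see [preprocess_stimulus()]).
#' @return List with `stimulus`, `prep` (frame sequence), `mapped` (named
#'   list of mapped gaze streams) and `labels` (`"case"`/`"control"`).
#' @export
simulate_cohort <- function(manifest = scene_manifest(),
                            n_per_group = 20,
                            params_case = phenotype_params(p_geometric = 0.8),
                            params_control = phenotype_params(p_geometric = 0.2),
                            sampling_rate = 120, seed = 1,
                            dim = c(200, 350), n_trim = 10) {
  stimulus <- generate_stimulus(manifest, seed = seed)
  prep <- preprocess_stimulus(stimulus, dim = dim, n_trim = n_trim)
  mapped <- list()
  labels <- character(0)
  for (g in c("case", "control")) {
    par <- if (g == "case") params_case else params_control
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      stream <- generate_gaze(stimulus, par, sampling_rate = sampling_rate,
                              subject_id = sid,
                              seed = seed * 997L + length(mapped) + 1L)
      mapped[[sid]] <- map_gaze(stream, prep)
      labels <- c(labels, g)
    }
  }
  list(stimulus = stimulus, prep = prep, mapped = mapped, labels = labels)
}
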