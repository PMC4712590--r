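# Synthetic cohort feature tables with Gaussian features; `shift` moves
# the sparse group's mean in the named regions only.
synth_table <- function(n_non = 15, n_sp = 8,
                        shift = c(posterior = 0, middle = 0, anterior = 0),
                        seed = 1) {
  set.seed(seed)
  subs <- sprintf("S%02d", seq_len(n_non + n_sp))
  labs <- rep(c("nonsparse", "sparse"), c(n_non, n_sp))
  rows <- list()
  for (i in seq_along(subs)) {
    for (r in c("posterior", "middle", "anterior")) {
      mu <- if (labs[i] == "sparse") shift[[r]] else 0
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = subs[i], region = r),
        as.data.frame(as.list(stats::setNames(stats::rnorm(13, mu),
                                              paste0("f", 1:13)))),
        data.frame(fc = stats::runif(1, 0.2, 0.3), label = labs[i]))
    }
  }
  do.call(rbind, rows)
}
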