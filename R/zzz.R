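.onLoad <- function(libname, pkgname) {
  # block-updating samplers for conjugate/GLM sub-structures; markedly
  # better mixing on the latent-confounder ridges than scalar Gibbs
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  invisible()
}
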