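# Shared fixtures: small phantoms and standard mask/material bundles used
# across the closed-loop tests.

default_phantom <- local({
  memo <- NULL
  function(...) {
    args <- list(...)
    if (length(args) == 0) {
      if (is.null(memo)) memo <<- make_cell_phantom(phantom_config())
      return(memo)
    }
    make_cell_phantom(phantom_config(...))
  }
})

standard_bundle <- function(ph) {
  list(
    materials = ph$materials[c("lipid", "medium", "coccolith")],
    masks = list(lipid = phantom_mask(ph, "lipid"),
                 medium = phantom_mask(ph, "medium"),
                 coccolith = phantom_mask(ph, "coccolith"))
  )
}

# independent eta oracle: direct polynomial arithmetic
eta_poly <- function(Z) -0.0254 + 1.6e-2 * Z - 1.86e-4 * Z^2 + 8.3e-7 * Z^3
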