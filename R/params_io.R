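#' Read and write the structured parameter file
#'
#' One versioned YAML schema covers the four parameter blocks: anatomy,
#' materials, excitation and numerics.  User-facing units are mm and Pa,
#' as in the objects themselves.
#'
#' @param anatomy An [anatomy_params()] object.
#' @param materials A [material_set()].
#' @param excitation An [excitation_spec()].
#' @param numerics A [slosh_numerics()].
#' @param path File path (YAML).
#' @return `write_slosh_params()` returns `path` invisibly;
#'   `read_slosh_params()` returns a list with elements `anatomy`,
#'   `materials`, `excitation`, `numerics` reconstructed through their
#'   constructors (so invariants are re-validated on load).
#' @export
write_slosh_params <- function(path,
                               anatomy = anatomy_params(),
                               materials = material_set(),
                               excitation = excitation_spec(),
                               numerics = slosh_numerics()) {
  doc <- list(
    schema = "sloshsim-params/1",
    anatomy = c(
      purrr::map(unclass(anatomy)[setdiff(names(anatomy),
                                          c("radius_anchors",
                                            "mri_like_syrinx_anchors"))],
                 identity),
      list(radius_anchors = as.list(anatomy$radius_anchors),
           mri_like_syrinx_anchors = as.list(anatomy$mri_like_syrinx_anchors))
    ),
    materials = unclass(materials),
    excitation = unclass(excitation),
    numerics = unclass(numerics)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_slosh_params
#' @export
read_slosh_params <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "sloshsim-params/1")) {
    stop("unrecognized parameter schema: ", doc$schema %||% "<missing>",
         call. = FALSE)
  }
  an <- doc$anatomy
  an$radius_anchors <- tibble::as_tibble(an$radius_anchors)
  an$mri_like_syrinx_anchors <- tibble::as_tibble(an$mri_like_syrinx_anchors)
  an$excitation_span_mm <- as.numeric(an$excitation_span_mm)
  an$region_bounds_mm <- as.numeric(an$region_bounds_mm)
  an$segment_lengths_mm <- as.numeric(an$segment_lengths_mm)
  list(
    anatomy = do.call(anatomy_params, an),
    materials = do.call(material_set, doc$materials),
    excitation = do.call(excitation_spec, doc$excitation),
    numerics = do.call(slosh_numerics, doc$numerics)
  )
}
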