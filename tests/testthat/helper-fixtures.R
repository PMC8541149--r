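# Lazily-built, session-cached fixtures.  Simulation runs are deterministic,
# so caching them across test files only saves time, never changes results.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

default_anatomy <- function() {
  fixture("anatomy", function() synthesize_anatomy(anatomy_params()))
}

config_by_name <- function(nm, anatomy = default_anatomy()) {
  if (nm == "baseline") return(make_baseline(anatomy))
  if (grepl("^S1-", nm)) {
    return(make_expanding_syrinx(anatomy, as.integer(sub("^S1-", "", nm))))
  }
  make_single_syrinx(anatomy, as.integer(sub("^S", "", nm)))
}

# full default-resolution run (1 mm, 0.4 s), cached by configuration name
full_run <- function(nm) {
  fixture(paste0("full_", nm), function() {
    run_simulation(assemble_system(config_by_name(nm)))
  })
}

smoke_run <- function(nm, ...) {
  key <- paste0("smoke_", nm, "_", rlang::hash(list(...)))
  fixture(key, function() {
    run_simulation(assemble_system(config_by_name(nm),
                                   numerics = slosh_numerics_smoke(...)))
  })
}

# the full 57-configuration suite at smoke resolution
smoke_suite <- function() {
  fixture("smoke_suite", function() {
    run_suite(default_anatomy(), numerics = slosh_numerics_smoke(),
              quiet = TRUE)
  })
}

# uniform straight-tube anatomy for wave-speed validation
uniform_anatomy <- function(r_cord = 3, gap = 1.5) {
  fixture(paste0("uniform_", r_cord, "_", gap), function() {
    synthesize_anatomy(anatomy_params(
      radius_anchors = tibble::tibble(
        x_mm = c(-15, 340), r_cord_mm = c(r_cord, r_cord),
        r_dura_inner_mm = c(r_cord + gap, r_cord + gap)
      ),
      mri_like_syrinx_anchors = tibble::tibble(
        x_mm = c(-15, 340), r_syrinx_mm = c(0, 0)
      )
    ))
  })
}
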