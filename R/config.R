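#' @include AllClasses.R AllGenerics.R
NULL

# Catalogue of parameters with their documented defaults.
.config_defaults <- function() list(
    expression_path = "",                 # reference files for CLI runs
    metadata_path = "",
    spatial_path = "",
    scenario = "expression_only",
    n_regions = 1L,                       # K
    grid_size = 20L,                      # B, boundary smoothness
    cells_per_region_per_type = list(),   # region -> (type -> count)
    window_method = "delaunay",
    buffer_radius = 5e-4,
    min_cell_distance = 5e-4,
    mh_iterations = 500000L,
    n_permutations = 2000L,
    max_cells_per_type_per_region = 2500L,
    depth_factor = 1,                     # sequencing depth multiplier
    evenness = 0,                         # nu, inflation exponent
    evenness_alpha_star = 0,              # alpha*, selection evenness weight
    inflation = 1.5,                      # eta
    neighbor_method = "knn",
    neighbor_param = 6,
    use_correlation = TRUE,
    colocalization_specs = list(),
    expression_cci_specs = list(),
    gene_pair_cci_specs = list(),
    regional_specs = list(),
    output_resolution = "single_cell",
    n_squares = 100L,
    seed = 1L,
    cap_max_counts = FALSE,
    match_depth = FALSE)

.config_enums <- list(
    scenario = c("paired", "expression_only", "unpaired"),
    window_method = c("delaunay", "rectangle", "convex", "sectioned_convex"),
    neighbor_method = c("knn", "delaunay", "distance"),
    output_resolution = c("single_cell", "multi_cell"))

.validate_config <- function(p) {
    for (nm in names(.config_enums))
        .assert(p[[nm]] %in% .config_enums[[nm]],
            "invalid value '%s' for %s (allowed: %s)", as.character(p[[nm]]),
            nm, paste(.config_enums[[nm]], collapse = ", "))
    .assert(p$n_regions >= 1L, "n_regions must be >= 1")
    .assert(p$grid_size >= 2L, "grid_size must be >= 2")
    .assert(p$depth_factor > 0, "depth_factor must be positive")
    .assert(p$inflation > 0, "inflation must be positive")
    .assert(p$buffer_radius >= 0, "buffer_radius must be non-negative")
    .assert(p$min_cell_distance >= 0, "min_cell_distance must be non-negative")
    .assert(p$mh_iterations >= 1L, "mh_iterations must be >= 1")
    .assert(p$n_permutations >= 1L, "n_permutations must be >= 1")
    .assert(p$max_cells_per_type_per_region >= 1L,
        "max_cells_per_type_per_region must be >= 1")
    for (s in p$expression_cci_specs)
        if (!is.null(s$gene_fraction))
            .assert(s$gene_fraction > 0 && s$gene_fraction <= 1,
                "gene_fraction must lie in (0, 1]")
    for (s in c(p$expression_cci_specs, p$gene_pair_cci_specs, p$regional_specs))
        if (!is.null(s$effect_sd))
            .assert(s$effect_sd >= 0, "effect_sd must be non-negative")
    invisible(p)
}

#' Build a simulation configuration
#'
#' Returns a \linkS4class{SimulationConfig} with every parameter at its
#' documented default, overridden by the named arguments supplied. One
#' config (plus its \code{seed}) fully determines a simulation run.
#'
#' Defaults: \code{grid_size} (region-boundary smoothness B) 20;
#' \code{mh_iterations} 500000; \code{n_permutations} 2000;
#' \code{max_cells_per_type_per_region} 2500 (model-fitting subsample cap);
#' \code{depth_factor} 1 (no depth change); \code{buffer_radius} and
#' \code{min_cell_distance} 5e-4 in reference coordinate units;
#' \code{evenness} (nu) 0; \code{inflation} (eta) 1.5.
#'
#' Perturbation/CCI spec blocks are lists of named lists:
#' \code{colocalization_specs} entries have \code{type_a}, \code{type_b},
#' \code{strength}; \code{expression_cci_specs} entries have \code{region}
#' (optional), \code{perturbed_type}, \code{neighbor_type},
#' \code{distance_threshold}, \code{genes} or \code{gene_fraction},
#' \code{effect_mean}, \code{effect_sd}; \code{gene_pair_cci_specs}
#' additionally have \code{gene_m}, \code{gene_n}, \code{bidirectional};
#' \code{regional_specs} have \code{region}, \code{perturbed_type},
#' \code{genes}/\code{gene_fraction}, \code{effect_mean}, \code{effect_sd}.
#'
#' @param ... parameter overrides (see \code{.config_defaults} in the
#'   source for the complete catalogue).
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(n_regions = 3, seed = 7)
#' configParam(cfg, "grid_size")
#' @export
simulationConfig <- function(...) {
    p <- .config_defaults()
    over <- list(...)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown)) {
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "), call. = FALSE)
        over <- over[setdiff(names(over), unknown)]
    }
    p[names(over)] <- over
    for (nm in c("n_regions", "grid_size", "mh_iterations", "n_permutations",
                 "max_cells_per_type_per_region", "n_squares", "seed"))
        p[[nm]] <- as.integer(p[[nm]])
    .validate_config(p)
    new("SimulationConfig", params = p)
}

#' Read a simulation configuration file
#'
#' Parses a YAML parameter file (flat key/value pairs plus repeated spec
#' blocks) into a \linkS4class{SimulationConfig}, filling documented
#' defaults for anything not given. An empty file yields the all-defaults
#' configuration. Unknown keys raise a warning and are dropped; invalid
#' enum values are errors.
#'
#' @param path path to a YAML file.
#' @return a \linkS4class{SimulationConfig}.
#' @export
readConfig <- function(path) {
    .assert(file.exists(path), "config file not found: %s", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    do.call(simulationConfig, vals)
}

#' Write a simulation configuration file
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path output YAML path.
#' @return invisibly, \code{path}.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config@params, path)
    invisible(path)
}
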