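#' Build a scenario from a YAML file or a nested list
#'
#' The YAML schema mirrors the scenario constructors; every field is
#' optional and defaults to the ideal monomer scenario. Example:
#'
#' ```yaml
#' roi: {x_min: 0, y_min: 0, x_max: 10000, y_max: 10000}   # nm
#' pattern:
#'   kind: circular_domains       # random|oligomer|circular_domains|
#'                                # rectangular_domains
#'   n_mer: 2
#'   domain_radius: 100           # nm
#'   rect_size: [80, 400]         # nm
#'   domain_density: 10           # per um^2
#'   fraction_in_domains: 1.0
#'   molecule_density: 75         # per um^2
#' labeling: {efficiency: 1.0, ratio: 0.5}
#' blink_red:                     # blink_blue takes the same fields
#'   family: lognormal            # lognormal|geometric|fixed|empirical
#'   meanlog: 1.504
#'   sdlog: 0.8
#'   frame_assignment: uniform    # uniform|burst
#'   n_frames: 10000
#' artifacts:
#'   localization_error_sigma: 30 # nm
#'   unspecific_label_density: 0  # per um^2 per channel
#'   background_density_red: 0
#'   background_density_blue: 0
#'   drift_total: [0, 0]          # nm over n_frames
#'   aberration_beta: 0
#'   aberration_center: [2500, 2500]
#' ```
#'
#' Bundled presets: `system.file("extdata/scenarios/ideal.yaml",
#' package = "clasta")` and `.../realistic.yaml`.
#'
#' @param path YAML file path (for `scenarioFromYAML`).
#' @param x Nested list (for `scenarioFromList`).
#' @return A [Scenario-class].
#' @export
scenarioFromYAML <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario file not found: %s", path))
  scenarioFromList(yaml::read_yaml(path))
}

#' @rdname scenarioFromYAML
#' @export
scenarioFromList <- function(x) {
  stopifnot(is.list(x))
  pick <- function(node, name, default) {
    if (is.null(node[[name]])) default else node[[name]]
  }
  roiNode <- x$roi
  roi <- if (is.null(roiNode)) RegionOfInterest(0, 0, 10000, 10000)
  else RegionOfInterest(pick(roiNode, "x_min", 0), pick(roiNode, "y_min", 0),
                        pick(roiNode, "x_max", 10000),
                        pick(roiNode, "y_max", 10000))
  p <- x$pattern
  pattern <- PatternSpec(
    kind = pick(p, "kind", "random"),
    nMer = pick(p, "n_mer", 1L),
    protomerOffset = pick(p, "protomer_offset", 0),
    domainRadius = pick(p, "domain_radius", 100),
    rectSize = unlist(pick(p, "rect_size", c(80, 400))),
    domainDensity = pick(p, "domain_density", 10),
    fractionInDomains = pick(p, "fraction_in_domains", 1),
    moleculeDensity = pick(p, "molecule_density", 75))
  l <- x$labeling
  labeling <- LabelingSpec(efficiency = pick(l, "efficiency", 1),
                           ratio = pick(l, "ratio", 0.5))
  blinkFromNode <- function(node) {
    tab <- pick(node, "table", NULL)
    BlinkModel(family = pick(node, "family", "lognormal"),
               meanlog = pick(node, "meanlog", log(3.2)),
               sdlog = pick(node, "sdlog", 0.8),
               mean = pick(node, "mean", 2),
               m = pick(node, "m", 1L),
               table = if (is.null(tab)) numeric(0) else unlist(tab),
               frameAssignment = pick(node, "frame_assignment", "uniform"),
               burstOn = pick(node, "burst_on", 2),
               burstOff = pick(node, "burst_off", 50),
               nFrames = pick(node, "n_frames", 10000L))
  }
  a <- x$artifacts
  artifacts <- ArtifactSpec(
    localizationErrorSigma = pick(a, "localization_error_sigma", 30),
    unspecificLabelDensity = pick(a, "unspecific_label_density", 0),
    backgroundDensityRed = pick(a, "background_density_red", 0),
    backgroundDensityBlue = pick(a, "background_density_blue", 0),
    backgroundBlink = if (is.null(a$background_blink))
      BlinkModel("geometric", mean = 2) else blinkFromNode(a$background_blink),
    driftTotal = unlist(pick(a, "drift_total", c(0, 0))),
    aberrationBeta = pick(a, "aberration_beta", 0),
    aberrationCenter = unlist(pick(a, "aberration_center", c(2500, 2500))))
  Scenario(roi = roi, pattern = pattern, labeling = labeling,
           blinkRed = blinkFromNode(x$blink_red),
           blinkBlue = blinkFromNode(x$blink_blue),
           artifacts = artifacts)
}
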