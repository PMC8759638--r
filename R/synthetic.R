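#' Synthetic CUT&RUN library specification
#'
#' Describes a genome with planted broad domains of nucleosomal signal and
#' planted DNA regulatory elements that shed clustered sub-nucleosomal
#' fragments, together with per-condition multiplicative effect profiles and a
#' replicate structure. [simulate_fragments()] turns a spec into fragment
#' libraries with known ground truth.
#'
#' Rates are expected fragment counts per kb per library (realized counts are
#' Poisson). Inside a planted domain the domain rate replaces the background
#' rate, so a condition's domain-scale multiplier maps directly onto the
#' relative change of in-domain signal.
#'
#' @param genome [genome_table()].
#' @param domains `data.frame` from [planted_domain()] rows.
#' @param elements `data.frame` from [planted_element()] rows.
#' @param background_rate Nucleosomal background, fragments/kb (genome-wide,
#'   outside domains).
#' @param short_background_rate Sub-nucleosomal background, fragments/kb
#'   (genome-wide).
#' @param conditions Named list of [effect_profile()]s; must contain the
#'   control.
#' @param replicates Number of replicates per condition.
#' @param seed Integer seed.
#' @param nucleosomal_length,subnucleosomal_length Length models,
#'   `c(mean, sd, min, max)` of a truncated normal in bp. Defaults:
#'   nucleosomal 185/25 truncated to \[147, 250\]; sub-nucleosomal 90/20
#'   truncated to \[50, 130\].
#' @param phased_nucleosomes Plant two nucleosomal hotspots flanking each
#'   element at `center +/- phase_offset_bp` (default on), emulating the
#'   phased nucleosomes that flank transcription-factor footprints.
#' @param phase_offset_bp Offset of the phased hotspots from element centers.
#' @return An object of class `synthetic_spec`.
#' @seealso [dhd_fixture()] for a ready-made mini-domain architecture.
#' @export
synthetic_spec <- function(genome,
                           domains = NULL,
                           elements = NULL,
                           background_rate = 25,
                           short_background_rate = 0.3,
                           conditions = list(control = effect_profile()),
                           replicates = 2L,
                           seed = 1L,
                           nucleosomal_length = c(mean = 185, sd = 25, min = 147, max = 250),
                           subnucleosomal_length = c(mean = 90, sd = 20, min = 50, max = 130),
                           phased_nucleosomes = TRUE,
                           phase_offset_bp = 120L) {
  if (is.null(domains)) {
    domains <- data.frame(id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          nucleosomal_rate = numeric(0), mark = character(0))
  }
  if (is.null(elements)) {
    elements <- data.frame(id = character(0), chrom = character(0),
                           center = integer(0), width = integer(0),
                           short_rate = numeric(0), position = character(0),
                           domain = character(0))
  }
  if (background_rate < 0 || short_background_rate < 0) {
    stop("synthetic_spec: rates must be >= 0", call. = FALSE)
  }
  .check_chroms(domains$chrom, genome, "planted domain")
  .check_chroms(elements$chrom, genome, "planted element")
  if (nrow(domains)) {
    if (any(domains$start < 0 | domains$end > genome[domains$chrom])) {
      stop("synthetic_spec: planted domain outside chromosome", call. = FALSE)
    }
    if (any(domains$nucleosomal_rate < background_rate)) {
      stop("synthetic_spec: domain rate below background_rate", call. = FALSE)
    }
  }
  if (nrow(elements) && any(elements$width < 1)) {
    stop("synthetic_spec: element width must be >= 1", call. = FALSE)
  }
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  structure(list(genome = genome, domains = domains, elements = elements,
                 background_rate = background_rate,
                 short_background_rate = short_background_rate,
                 conditions = conditions,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 nucleosomal_length = nucleosomal_length,
                 subnucleosomal_length = subnucleosomal_length,
                 phased_nucleosomes = isTRUE(phased_nucleosomes),
                 phase_offset_bp = as.integer(phase_offset_bp)),
            class = "synthetic_spec")
}

#' Planted domain row
#'
#' @param id Domain identifier.
#' @param chrom,start,end Interval (0-based half-open).
#' @param nucleosomal_rate Expected nucleosomal fragments per kb inside the
#'   domain (replaces the background rate there).
#' @param mark Histone-mark label (informational), e.g. `"H3K27me3"`.
#' @return One-row `data.frame`.
#' @export
planted_domain <- function(id, chrom, start, end, nucleosomal_rate,
                           mark = "H3K27me3") {
  data.frame(id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), nucleosomal_rate = nucleosomal_rate,
             mark = mark, stringsAsFactors = FALSE)
}

#' Planted regulatory element row
#'
#' @param id Element identifier.
#' @param chrom Chromosome.
#' @param center Footprint center (0-based bp).
#' @param width Footprint width in bp; fragment midpoints are jittered
#'   uniformly within `center +/- width/2`.
#' @param short_rate Expected sub-nucleosomal fragment count per library.
#' @param position `"five_prime_border"`, `"three_prime_border"`,
#'   `"internal"`, or `"none"` (relative to the owning domain).
#' @param domain Owning domain id or `NA`.
#' @return One-row `data.frame`.
#' @export
planted_element <- function(id, chrom, center, width, short_rate,
                            position = c("none", "five_prime_border",
                                         "three_prime_border", "internal"),
                            domain = NA_character_) {
  position <- match.arg(position)
  data.frame(id = id, chrom = chrom, center = as.integer(center),
             width = as.integer(width), short_rate = short_rate,
             position = position, domain = domain, stringsAsFactors = FALSE)
}

#' Multiplicative condition effect profile
#'
#' Knockdown-style condition effects are multiplicative on planted rates, so a
#' profile maps directly onto percent-change readouts (scale 0.65 is a 35%
#' reduction of in-domain signal).
#'
#' @param global_domain_scale Multiplier applied to every domain's nucleosomal
#'   rate.
#' @param domain_scale Named numeric vector of per-domain overrides
#'   (domain id -> multiplier), replacing the global scale for those domains.
#' @param element_scale_default Multiplier applied to every element's
#'   short-fragment rate.
#' @param element_scale Named numeric vector of per-element overrides.
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(global_domain_scale = 1,
                           domain_scale = numeric(0),
                           element_scale_default = 1,
                           element_scale = numeric(0)) {
  if (global_domain_scale < 0 || element_scale_default < 0 ||
      any(domain_scale < 0) || any(element_scale < 0)) {
    stop("effect_profile: multipliers must be >= 0", call. = FALSE)
  }
  structure(list(global_domain_scale = global_domain_scale,
                 domain_scale = domain_scale,
                 element_scale_default = element_scale_default,
                 element_scale = element_scale),
            class = "effect_profile")
}

# Integer truncated-normal sampler via inverse CDF (deterministic given RNG
# state); values rounded then clamped into [min, max].
rtrunc_norm_int <- function(n, mean, sd, min, max) {
  if (n == 0L) return(integer(0))
  lo <- stats::pnorm(min, mean, sd)
  hi <- stats::pnorm(max, mean, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  pmin(pmax(as.integer(round(x)), as.integer(min)), as.integer(max))
}

# one library (condition x replicate) for a spec; assumes RNG state is set
.simulate_library <- function(spec, condition, replicate_name) {
  prof <- spec$conditions[[condition]]
  nl <- spec$nucleosomal_length
  sl <- spec$subnucleosomal_length
  chrom <- character(0); mid <- integer(0); len <- integer(0)

  add <- function(chr, m, l) {
    chrom <<- c(chrom, rep(chr, length(m)))
    mid <<- c(mid, as.integer(m))
    len <<- c(len, as.integer(l))
  }

  for (chr in names(spec$genome)) {
    chrlen <- spec$genome[[chr]]
    dom <- spec$domains[spec$domains$chrom == chr, , drop = FALSE]
    # nucleosomal background, thinned inside domains (domain rate replaces it)
    n_bg <- stats::rpois(1L, spec$background_rate * chrlen / 1000)
    if (n_bg > 0L) {
      m <- as.integer(floor(stats::runif(n_bg, 0, chrlen)))
      if (nrow(dom)) {
        inside <- rep(FALSE, n_bg)
        for (k in seq_len(nrow(dom))) {
          inside <- inside | (m >= dom$start[k] & m < dom$end[k])
        }
        m <- m[!inside]
      }
      add(chr, m, rtrunc_norm_int(length(m), nl["mean"], nl["sd"], nl["min"], nl["max"]))
    }
    # sub-nucleosomal background (genome-wide)
    n_sbg <- stats::rpois(1L, spec$short_background_rate * chrlen / 1000)
    if (n_sbg > 0L) {
      m <- as.integer(floor(stats::runif(n_sbg, 0, chrlen)))
      add(chr, m, rtrunc_norm_int(n_sbg, sl["mean"], sl["sd"], sl["min"], sl["max"]))
    }
    # planted domains
    for (k in seq_len(nrow(dom))) {
      scale <- prof$global_domain_scale
      if (dom$id[k] %in% names(prof$domain_scale)) scale <- prof$domain_scale[[dom$id[k]]]
      n_d <- stats::rpois(1L, dom$nucleosomal_rate[k] * scale *
                            (dom$end[k] - dom$start[k]) / 1000)
      if (n_d > 0L) {
        m <- as.integer(floor(stats::runif(n_d, dom$start[k], dom$end[k])))
        add(chr, m, rtrunc_norm_int(n_d, nl["mean"], nl["sd"], nl["min"], nl["max"]))
      }
    }
    # planted elements: clustered short fragments plus optional phased
    # nucleosomal hotspots flanking the footprint
    ele <- spec$elements[spec$elements$chrom == chr, , drop = FALSE]
    for (k in seq_len(nrow(ele))) {
      escale <- prof$element_scale_default
      if (ele$id[k] %in% names(prof$element_scale)) escale <- prof$element_scale[[ele$id[k]]]
      n_e <- stats::rpois(1L, ele$short_rate[k] * escale)
      if (n_e > 0L) {
        half <- ele$width[k] / 2
        m <- ele$center[k] + as.integer(round(stats::runif(n_e, -half, half)))
        add(chr, m, rtrunc_norm_int(n_e, sl["mean"], sl["sd"], sl["min"], sl["max"]))
      }
      if (spec$phased_nucleosomes) {
        dscale <- prof$global_domain_scale
        if (!is.na(ele$domain[k]) && ele$domain[k] %in% names(prof$domain_scale)) {
          dscale <- prof$domain_scale[[ele$domain[k]]]
        }
        for (side in c(-1L, 1L)) {
          n_p <- stats::rpois(1L, ele$short_rate[k] * dscale / 2)
          if (n_p > 0L) {
            m <- ele$center[k] + side * spec$phase_offset_bp +
              as.integer(round(stats::rnorm(n_p, 0, 20)))
            add(chr, m, rtrunc_norm_int(n_p, nl["mean"], nl["sd"], nl["min"], nl["max"]))
          }
        }
      }
    }
  }

  start <- mid - len %/% 2L
  end <- start + len
  keep <- start >= 0L & end <= spec$genome[chrom]
  fragments(chrom[keep], start[keep], end[keep],
            sample = condition, replicate = replicate_name)
}

#' Simulate fragment libraries from a synthetic spec
#'
#' Generates one fragment library per (condition, replicate). Nucleosomal
#' fragment lengths follow a truncated normal (default mean 185, sd 25, range
#' 147-250bp); element-derived sub-nucleosomal lengths a truncated normal
#' (default mean 90, sd 20, range 50-130bp). Element fragment midpoints are
#' jittered uniformly within the footprint. All counts are Poisson around the
#' configured (condition-scaled) rates. Fully reproducible from the seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (defaults to `spec$seed`). Each library draws from
#'   a child seed derived deterministically from it, so libraries are
#'   independently reproducible.
#' @return Named list of fragment tables, names `"<condition>.<replicate>"`
#'   (replicates named `rep1`, `rep2`, ...).
#' @export
simulate_fragments <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- list()
  idx <- 0L
  for (condition in names(spec$conditions)) {
    for (r in seq_len(spec$replicates)) {
      idx <- idx + 1L
      child <- (as.numeric(seed) * 1000 + idx * 7919) %% 2147483647
      rep_name <- paste0("rep", r)
      out[[paste(condition, rep_name, sep = ".")]] <-
        with_seed(child, .simulate_library(spec, condition, rep_name))
    }
  }
  out
}

#' Ground-truth manifest of a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return List with planted `domains`, `elements`, per-condition expected
#'   in-domain percent changes versus the first condition, and any `notes`
#'   attached to the spec.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ctrl <- names(spec$conditions)[1L]
  expected <- lapply(names(spec$conditions), function(cond) {
    prof <- spec$conditions[[cond]]
    sc <- rep(prof$global_domain_scale, nrow(spec$domains))
    names(sc) <- spec$domains$id
    ov <- intersect(names(prof$domain_scale), names(sc))
    sc[ov] <- prof$domain_scale[ov]
    100 * (sc - 1)
  })
  names(expected) <- names(spec$conditions)
  list(domains = spec$domains, elements = spec$elements,
       control = ctrl, expected_domain_percent_change = expected,
       notes = attr(spec, "notes"))
}

#' Mini-domain fixture: a dhd-like architecture with ground truth
#'
#' A single 4Mb chromosome carrying (i) a 5450bp repressive-mark mini-domain
#' with exactly two border regulatory elements and no internal elements — the
#' dhd-locus architecture — and (ii) a large 40kb control domain with both
#' border and internal elements for contrast. Element placement inside the
#' mini-domain reproduces the locus geometry: the 5' element (92bp footprint)
#' is centered 151bp inside the 5' domain edge, the 3' element (148bp
#' footprint) 91bp inside the 3' edge. The published coordinates for the locus
#' print a domain interval inconsistent with the stated ~5450bp width; the
#' fixture resolves this in favor of the width, deriving the 5' edge as
#' (3' edge - 5450), and records the choice in its ground-truth notes.
#'
#' Conditions mirror the knockdown effect regimes of the study system:
#' a control, a strong domain effect (scale 0.65, i.e. -35%), an intermediate
#' one (0.80, -20%), and two mild ones (0.95, -5%) — one of which additionally
#' scales only the mini-domain border elements — plus a condition that leaves
#' elements intact but raises the mini-domain (1.20). Element short-fragment
#' scales follow the strong (~63%) reductions seen for the corresponding
#' knockdowns.
#'
#' @param depth Multiplier on all fragment rates (1 = default study depth).
#' @return A [synthetic_spec()] with a `notes` attribute.
#' @export
dhd_fixture <- function(depth = 1) {
  gt <- genome_table(c(X = 4e6))
  mini_end <- 2005450L
  mini_start <- mini_end - 5450L
  domains <- rbind(
    planted_domain("mini", "X", mini_start, mini_end, 600 * depth, "H3K27me3"),
    planted_domain("ctrl", "X", 3000000L, 3040000L, 300 * depth, "H3K27me3")
  )
  elements <- rbind(
    planted_element("mini_5p", "X", mini_start + 151L, 92L, 80 * depth,
                    "five_prime_border", "mini"),
    planted_element("mini_3p", "X", mini_end - 91L, 148L, 80 * depth,
                    "three_prime_border", "mini"),
    planted_element("ctrl_5p", "X", 3000150L, 100L, 80 * depth,
                    "five_prime_border", "ctrl"),
    planted_element("ctrl_3p", "X", 3039850L, 100L, 80 * depth,
                    "three_prime_border", "ctrl"),
    planted_element("ctrl_in1", "X", 3010000L, 100L, 80 * depth, "internal", "ctrl"),
    planted_element("ctrl_in2", "X", 3020000L, 100L, 80 * depth, "internal", "ctrl"),
    planted_element("ctrl_in3", "X", 3030000L, 100L, 80 * depth, "internal", "ctrl")
  )
  conditions <- list(
    control  = effect_profile(),
    ez_kd    = effect_profile(0.65, element_scale_default = 0.37),
    snr1_kd  = effect_profile(0.80, element_scale_default = 0.37),
    sin3a_kd = effect_profile(0.95, element_scale_default = 0.37),
    mod_kd   = effect_profile(0.95,
                              element_scale = c(mini_5p = 0.4, mini_3p = 0.4)),
    lid_kd   = effect_profile(0.95, domain_scale = c(mini = 1.20))
  )
  spec <- synthetic_spec(genome = gt, domains = domains, elements = elements,
                         background_rate = 25 * depth,
                         short_background_rate = 0.3 * depth,
                         conditions = conditions, replicates = 2L, seed = 1L)
  attr(spec, "notes") <- paste(
    "mini-domain 5' edge derived as 3' edge - 5450bp: the source locus prints",
    "a domain interval inconsistent with its stated ~5450bp width, resolved",
    "in favor of the width. Border element centers sit 151bp (5', 92bp",
    "footprint) and 91bp (3', 148bp footprint) inside the domain edges,",
    "matching the published element spans relative to the derived edges.")
  spec
}
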