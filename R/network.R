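#' Build the intracellular reaction network
#'
#' Assembles the stochastic reaction network of one cell.
#'
#' The `"reduced"` variant carries the four expression species
#' (`mRNA_MGMT`, `MGMT`, `mRNA_REF`, `REF`) with constitutive
#' transcription (`b1`), mRNA decay (`d`), translation (`b2`), optional
#' first-order protein decay (`d2`, off when 0), and a single death
#' channel whose propensity is the pseudo-steady-state rate
#' `f2 = kd2 * kd*tmz / (kd*tmz + s*MGMT)`, plus the basal rate `eps`
#' when `include_basal` (the data-constrained model's death channel; the
#' general model uses the bare `f2`).
#'
#' The `"full"` variant resolves the fast DNA damage/repair cycle
#' explicitly: a binary `DNA_DAM` state is damaged at `kd * tmz` (from
#' the undamaged state, by conservation `DNA = 1 - DNA_DAM`) and
#' repaired at `s * MGMT`, and death fires at `kd2 * DNA_DAM`.
#' Transcription proceeds from both gene states at `b1`, which under the
#' conservation relation collapses to a single constant-rate channel per
#' gene.  The full variant is the small-scale oracle for the reduced
#' one; tau-leaping is not offered for it (the binary gene state is not
#' a Poisson-update species).
#'
#' @param params a [model_params()] object.
#' @param variant `"reduced"` (pseudo-steady-state death) or `"full"`
#'   (explicit damage/repair cycle).
#' @param include_basal add the basal death rate `eps` to the death
#'   channel?  Defaults to `TRUE` when `params$eps > 0`.
#' @return An object of class `phenosel_network`.
#' @export
#' @examples
#' net <- build_network(params_general(), "reduced")
#' nrow(net$reactions)  # 7 channels when d2 = 0
build_network <- function(params, variant = c("reduced", "full"),
                          include_basal = NULL) {
  stopifnot(inherits(params, "phenosel_params"))
  variant <- match.arg(variant)
  if (is.null(include_basal)) include_basal <- params$eps > 0
  eps_term <- if (include_basal) params$eps else 0

  species <- c("mRNA_MGMT", "MGMT", "mRNA_REF", "REF")
  if (variant == "full") species <- c(species, "DNA_DAM")
  ns <- length(species)
  idx <- function(nm) match(nm, species) - 1L  # 0-based for the kernel

  ch <- list()
  add <- function(label, kind, rate, dep1 = -1L, dep2 = -1L,
                  stoich = integer(ns), pmat = c(0, 0, 0),
                  is_death = FALSE) {
    ch[[length(ch) + 1L]] <<- list(label = label, kind = kind, rate = rate,
                                   dep1 = dep1, dep2 = dep2, stoich = stoich,
                                   pmat = pmat, is_death = is_death)
  }
  unit <- function(nm, v = 1L) {
    s <- integer(ns); s[idx(nm) + 1L] <- v; s
  }

  add("transcription_MGMT", 0L, params$b1, stoich = unit("mRNA_MGMT"))
  add("decay_mRNA_MGMT", 1L, params$d, dep1 = idx("mRNA_MGMT"),
      stoich = unit("mRNA_MGMT", -1L))
  add("translation_MGMT", 1L, params$b2, dep1 = idx("mRNA_MGMT"),
      stoich = unit("MGMT"))
  add("transcription_REF", 0L, params$b1, stoich = unit("mRNA_REF"))
  add("decay_mRNA_REF", 1L, params$d, dep1 = idx("mRNA_REF"),
      stoich = unit("mRNA_REF", -1L))
  add("translation_REF", 1L, params$b2, dep1 = idx("mRNA_REF"),
      stoich = unit("REF"))
  if (params$d2 > 0) {
    add("decay_MGMT", 1L, params$d2, dep1 = idx("MGMT"),
        stoich = unit("MGMT", -1L))
    add("decay_REF", 1L, params$d2, dep1 = idx("REF"),
        stoich = unit("REF", -1L))
  }
  if (variant == "reduced") {
    add("death", 4L, params$kd2, dep1 = idx("MGMT"),
        pmat = c(params$kd, params$s, eps_term), is_death = TRUE)
  } else {
    add("dna_damage", 3L, params$kd, dep1 = idx("DNA_DAM"),
        stoich = unit("DNA_DAM"))
    add("dna_repair", 2L, params$s, dep1 = idx("MGMT"),
        dep2 = idx("DNA_DAM"), stoich = unit("DNA_DAM", -1L))
    add("death", 1L, params$kd2, dep1 = idx("DNA_DAM"), is_death = TRUE)
    if (eps_term > 0) add("death_basal", 0L, eps_term, is_death = TRUE)
  }

  reactions <- tibble::tibble(
    label = purrr::map_chr(ch, "label"),
    kind = purrr::map_int(ch, "kind"),
    rate = purrr::map_dbl(ch, "rate"),
    is_death = purrr::map_lgl(ch, "is_death")
  )
  structure(
    list(
      species = species,
      reactions = reactions,
      variant = variant,
      include_basal = include_basal,
      stoich = do.call(rbind, purrr::map(ch, "stoich")),
      kind = purrr::map_int(ch, "kind"),
      dep1 = as.integer(purrr::map_dbl(ch, "dep1")),
      dep2 = as.integer(purrr::map_dbl(ch, "dep2")),
      rate = purrr::map_dbl(ch, "rate"),
      pmat = do.call(rbind, purrr::map(ch, "pmat")),
      is_death = purrr::map_lgl(ch, "is_death"),
      partition = species != "DNA_DAM"
    ),
    class = "phenosel_network"
  )
}

#' @export
print.phenosel_network <- function(x, ...) {
  cat("<phenosel_network> ", x$variant, " variant, ",
      length(x$species), " species, ", nrow(x$reactions), " channels\n",
      sep = "")
  print(x$reactions)
  invisible(x)
}

#' Custom birth-death style network
#'
#' Low-level constructor for arbitrary mass-action networks, used for
#' engine verification against closed forms (e.g. the Poisson
#' stationary law of a pure birth-death process).  Channels are given as
#' a list of lists with fields `stoich` (integer change vector),
#' `kind` (0 = constant, 1 = linear in species `dep1`), `rate`, `dep1`
#' (1-based species index or NA), and optional `is_death`.
#'
#' @param species character vector of species names.
#' @param channels list of channel descriptors (see above).
#' @return A `phenosel_network` object.
#' @export
#' @examples
#' bd <- custom_network("X", list(
#'   list(stoich = 1L, kind = 0L, rate = 0.1),
#'   list(stoich = -1L, kind = 1L, rate = 0.01, dep1 = 1)
#' ))
custom_network <- function(species, channels) {
  ns <- length(species)
  get0i <- function(cc, nm, default) {
    v <- cc[[nm]]
    if (is.null(v) || is.na(v)) default else v
  }
  stoich <- do.call(rbind, purrr::map(channels, function(cc) {
    s <- as.integer(cc$stoich)
    if (length(s) != ns) stop("stoich length must match species",
                              call. = FALSE)
    s
  }))
  structure(
    list(
      species = species,
      reactions = tibble::tibble(
        label = purrr::map_chr(seq_along(channels),
                               ~ paste0("channel_", .x)),
        kind = purrr::map_int(channels, ~ as.integer(.x$kind)),
        rate = purrr::map_dbl(channels, "rate"),
        is_death = purrr::map_lgl(channels, ~ isTRUE(.x$is_death))
      ),
      variant = "custom",
      include_basal = FALSE,
      stoich = stoich,
      kind = purrr::map_int(channels, ~ as.integer(.x$kind)),
      dep1 = purrr::map_int(channels,
                            ~ as.integer(get0i(.x, "dep1", 0L)) - 1L),
      dep2 = purrr::map_int(channels,
                            ~ as.integer(get0i(.x, "dep2", 0L)) - 1L),
      rate = purrr::map_dbl(channels, "rate"),
      pmat = matrix(0, nrow = length(channels), ncol = 3),
      is_death = purrr::map_lgl(channels, ~ isTRUE(.x$is_death)),
      partition = rep(TRUE, ns)
    ),
    class = "phenosel_network"
  )
}

# flatten for the C++ kernel
net_as_list <- function(net) {
  list(
    stoich = net$stoich,
    kind = net$kind,
    dep1 = net$dep1,
    dep2 = net$dep2,
    rate = net$rate,
    pmat = net$pmat,
    is_death = net$is_death,
    partition = net$partition
  )
}
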