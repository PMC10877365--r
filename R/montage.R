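#' The 19-channel 10-20 EEG montage with anatomical groupings
#'
#' Builds the standard 19-electrode 10-20 scalp montage used throughout the
#' package, together with its anatomical structure: the lobe each channel
#' belongs to (frontal, parietal, temporal, occipital, or the central strip)
#' and its hemisphere (left, right, or midline).  All channel matrices and
#' subset encodings in the package use the canonical channel order fixed
#' here, which makes subset bitmasks and selection tie-breaking
#' deterministic.
#'
#' Channel names follow the 10-20 convention: the letter encodes the region
#' (F frontal, T temporal, C central, P parietal, O occipital), odd digits
#' are left-hemisphere, even digits right-hemisphere, and `z` marks the
#' midline.  The midline electrodes Fz, Cz and Pz belong to no hemisphere.
#'
#' @return An object of class `ChannelMontage`: a list with
#'   \describe{
#'     \item{channels}{character vector of the 19 channel names in canonical
#'       order.}
#'     \item{region_of}{named character vector mapping each channel to a lobe
#'       abbreviation (`FL`, `PL`, `TL`, `OL`, `C`).}
#'     \item{hemisphere_of}{named character vector mapping each channel to
#'       `LH`, `RH` or `midline`.}
#'   }
#' @examples
#' m <- standard_montage()
#' m$channels
#' table(m$region_of)
#' @export
standard_montage <- function() {
  channels <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                "O1", "O2", "F7", "F8", "T7", "T8", "P7", "P8",
                "Fz", "Cz", "Pz")
  region <- c(
    Fp1 = "FL", Fp2 = "FL", F3 = "FL", F4 = "FL", F7 = "FL", F8 = "FL",
    Fz = "FL",
    P3 = "PL", P4 = "PL", P7 = "PL", P8 = "PL", Pz = "PL",
    T7 = "TL", T8 = "TL",
    O1 = "OL", O2 = "OL",
    C3 = "C", C4 = "C", Cz = "C"
  )
  hemi <- c(
    Fp1 = "LH", F3 = "LH", F7 = "LH", C3 = "LH", T7 = "LH", P3 = "LH",
    P7 = "LH", O1 = "LH",
    Fp2 = "RH", F4 = "RH", F8 = "RH", C4 = "RH", T8 = "RH", P4 = "RH",
    P8 = "RH", O2 = "RH",
    Fz = "midline", Cz = "midline", Pz = "midline"
  )
  m <- list(channels = channels,
            region_of = region[channels],
            hemisphere_of = hemi[channels])
  class(m) <- "ChannelMontage"
  m
}

#' @export
print.ChannelMontage <- function(x, ...) {
  cat("ChannelMontage: ", length(x$channels), " channels (10-20 layout)\n",
      sep = "")
  cat("  ", paste(x$channels, collapse = " "), "\n", sep = "")
  invisible(x)
}

# Lobe letters in the order used to name lobe combinations (F, T, C, P, O);
# combination names concatenate these letters, e.g. "TPO", "FCPO".
lobe_letter_order <- c(FL = "F", TL = "T", C = "C", PL = "P", OL = "O")

#' Construct a named channel group
#'
#' A `ChannelGroup` is a named, de-duplicated subset of montage channels
#' tagged with the experiment family it belongs to (`e1` hemispheres, `e2`
#' lobes, `e3` lobe triples, `e4` lobe quadruples, `e5` singletons, or
#' `custom`).  Members are stored in canonical montage order.
#'
#' @param name Text label, e.g. `"LH"`, `"FL"`, `"TPO"`, `"T7"`, `"ALL"`.
#' @param members Character vector of channel names; must be a non-empty
#'   subset of the montage channels.
#' @param experiment Experiment tag; one of `"e1"`..`"e5"` or `"custom"`.
#' @param montage A [standard_montage()] object.
#' @return A `ChannelGroup` object.
#' @export
channel_group <- function(name, members, experiment = "custom",
                          montage = standard_montage()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unique(members)
  if (length(members) == 0L)
    stop("channel group '", name, "' must have at least one member")
  unknown <- setdiff(members, montage$channels)
  if (length(unknown))
    stop("unknown channel(s) in group '", name, "': ",
         paste(unknown, collapse = ", "))
  experiment <- match.arg(experiment,
                          c("e1", "e2", "e3", "e4", "e5", "custom"))
  g <- list(name = name,
            members = intersect(montage$channels, members),
            experiment = experiment)
  class(g) <- "ChannelGroup"
  g
}

#' @export
print.ChannelGroup <- function(x, ...) {
  cat("ChannelGroup ", x$name, " [", x$experiment, "]: ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Catalogue of all anatomical channel groups
#'
#' Enumerates the channel groupings evaluated in the location-based
#' experiments: the full 19-channel set, the two hemispheres (e1), the five
#' lobe-level regions (e2; the central strip is treated as a lobe-level
#' group), all 10 lobe triples (e3), all 5 lobe quadruples (e4), and the 19
#' single-channel groups (e5) — 42 groups in total.  Lobe-combination names
#' concatenate the lobe letters in the fixed order F, T, C, P, O (so the
#' triple of temporal, parietal and occipital lobes is `"TPO"`).
#'
#' @param montage A [standard_montage()] object.
#' @return A named list of [channel_group()] objects, length 42.
#' @examples
#' cat42 <- build_group_catalogue()
#' length(cat42)
#' cat42$TPO$members
#' @export
build_group_catalogue <- function(montage = standard_montage()) {
  lobes <- names(lobe_letter_order)
  lobe_members <- lapply(lobes, function(l)
    montage$channels[montage$region_of == l])
  names(lobe_members) <- lobes

  groups <- list(channel_group("ALL", montage$channels, "custom", montage))

  for (h in c("LH", "RH"))
    groups <- c(groups, list(channel_group(
      h, montage$channels[montage$hemisphere_of == h], "e1", montage)))

  for (l in lobes)
    groups <- c(groups, list(channel_group(l, lobe_members[[l]], "e2",
                                           montage)))

  combo_group <- function(idx, tag) {
    nm <- paste(lobe_letter_order[lobes[idx]], collapse = "")
    channel_group(nm, unlist(lobe_members[idx], use.names = FALSE), tag,
                  montage)
  }
  for (idx in utils::combn(5L, 3L, simplify = FALSE))
    groups <- c(groups, list(combo_group(idx, "e3")))
  for (idx in utils::combn(5L, 4L, simplify = FALSE))
    groups <- c(groups, list(combo_group(idx, "e4")))

  for (ch in montage$channels)
    groups <- c(groups, list(channel_group(ch, ch, "e5", montage)))

  names(groups) <- vapply(groups, `[[`, character(1), "name")
  groups
}

#' Look up a channel group by name
#'
#' @param catalogue A list of `ChannelGroup`s, e.g. from
#'   [build_group_catalogue()].
#' @param name Group label to retrieve.
#' @return The matching `ChannelGroup`.
#' @export
group_by_name <- function(catalogue, name) {
  labels <- vapply(catalogue, `[[`, character(1), "name")
  hit <- which(labels == name)
  if (length(hit) != 1L)
    stop("unknown group '", name, "'; valid labels: ",
         paste(labels, collapse = ", "))
  catalogue[[hit]]
}

#' Write / read a montage or group catalogue as a YAML config
#'
#' Human-readable serialisation of the montage definition and a group
#' catalogue, so channel groupings can be inspected and edited outside R.
#'
#' @param montage A `ChannelMontage`.
#' @param catalogue Optional group catalogue to include.
#' @param path File path to write to / read from.
#' @return `write_montage_config` returns `path` invisibly;
#'   `read_montage_config` returns a list with elements `montage` and
#'   (if present in the file) `catalogue`.
#' @export
write_montage_config <- function(montage, path, catalogue = NULL) {
  cfg <- list(channels = montage$channels,
              region_of = as.list(montage$region_of),
              hemisphere_of = as.list(montage$hemisphere_of))
  if (!is.null(catalogue)) {
    cfg$groups <- lapply(catalogue, function(g)
      list(members = g$members, experiment = g$experiment))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_montage_config
#' @export
read_montage_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- list(channels = as.character(cfg$channels),
            region_of = unlist(cfg$region_of)[as.character(cfg$channels)],
            hemisphere_of =
              unlist(cfg$hemisphere_of)[as.character(cfg$channels)])
  class(m) <- "ChannelMontage"
  out <- list(montage = m)
  if (!is.null(cfg$groups)) {
    out$catalogue <- lapply(names(cfg$groups), function(nm)
      channel_group(nm, as.character(cfg$groups[[nm]]$members),
                    cfg$groups[[nm]]$experiment, m))
    names(out$catalogue) <- names(cfg$groups)
  }
  out
}
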