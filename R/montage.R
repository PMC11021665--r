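#' @include AllClasses.R
NULL

# Standard extended 10-20 coordinate table, head-circle convention: vertex
# (Cz) at the origin, row spacing 0.25 front-to-back, column spacing 0.2
# left-to-right (odd numbers left / even right, z on the midline). A flat
# grid is used rather than a spherical projection; only relative distances
# matter (Laplacian adjacency and the simulator's spatial falloff).
standardPositionTable <- function() {
  rows <- list(
    Fp = list(y = 1.00, labs = c("Fp1", "Fpz", "Fp2")),
    AF = list(y = 0.75, labs = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    F  = list(y = 0.50, labs = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    FC = list(y = 0.25, labs = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
    C  = list(y = 0.00, labs = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    CP = list(y = -0.25, labs = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz",
                                  "CP2", "CP4", "CP6", "TP8", "TP10")),
    P  = list(y = -0.50, labs = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    PO = list(y = -0.75, labs = c("PO7", "PO3", "POz", "PO4", "PO8")),
    O  = list(y = -1.00, labs = c("O1", "Oz", "O2")),
    I  = list(y = -1.25, labs = "Iz")
  )
  xFor <- function(lab) {
    num <- sub("^[A-Za-z]+", "", lab)
    if (num == "z" || num == "") return(0)
    n <- as.integer(num)
    side <- if (n %% 2 == 1) -1 else 1
    k <- ceiling(n / 2)
    if (grepl("^(T|FT|TP)", lab) && n %in% c(7, 8)) k <- 4   # temporal line
    if (n %in% c(9, 10)) k <- 5
    side * 0.2 * k
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r$labs, x = vapply(r$labs, xFor, numeric(1)),
               y = r$y, stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- out$label
  out
}

# 64 channels of the actiCap-style extended 10-20 layout used throughout
standardChannelSet <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
}

#' The 20 sensorimotor channels used as detector inputs
#'
#' Channel labels over the sensorimotor cortex, in the canonical order the
#' preprocessing chain emits them.
#' @return character vector of 20 labels.
#' @export
sensorimotorChannels <- function() {
  c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
}

#' Build and validate a montage from channel labels
#'
#' Labels recognized from the extended 10-20 system receive scalp
#' coordinates and a symmetric nearest-neighbor map (orthogonal grid
#' neighbors, the "small Laplacian" neighborhood); unrecognized labels are
#' kept, flagged in the `unrecognized` attribute, and get no neighbors.
#'
#' @param labels character vector of channel names; duplicates are an error.
#' @param neighborRadius maximum scalp distance (head-circle units) for two
#'   channels to count as Laplacian neighbors.
#' @return a [Montage-class]; `attr(x, "unrecognized")` lists unknown labels.
#' @examples
#' m <- validateMontage(c("C3", "Cz", "C4", "CP1", "FC1"))
#' channelNames(m)
#' @export
validateMontage <- function(labels, neighborRadius = 0.27) {
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  tab <- standardPositionTable()
  pos <- matrix(NA_real_, length(labels), 2,
                dimnames = list(labels, c("x", "y")))
  known <- labels %in% rownames(tab)
  pos[known, ] <- as.matrix(tab[labels[known], c("x", "y")])
  nb <- setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) nb[[i]] <- character(0)
  ki <- which(known)
  if (length(ki) > 1) {
    d <- as.matrix(stats::dist(pos[ki, , drop = FALSE]))
    for (a in seq_along(ki)) {
      hits <- ki[which(d[a, ] > 1e-9 & d[a, ] <= neighborRadius)]
      nb[[labels[ki[a]]]] <- labels[hits]
    }
  }
  m <- new("Montage", labels = as.character(labels), positions = pos,
           neighbors = nb)
  attr(m, "unrecognized") <- labels[!known]
  m
}

#' The standard 64-channel montage
#'
#' @return a [Montage-class] with the 64 extended 10-20 labels, including
#'   all 20 sensorimotor channels.
#' @export
standardMontage <- function() validateMontage(standardChannelSet())

# scalp distance of every montage channel from a center channel; channels
# without coordinates are infinitely far (zero topographic gain)
montageDistances <- function(montage, center) {
  if (!center %in% montage@labels) stop("center channel not in montage: ", center)
  p <- montage@positions
  d <- sqrt((p[, 1] - p[center, 1])^2 + (p[, 2] - p[center, 2])^2)
  d[is.na(d)] <- Inf
  setNames(d, montage@labels)
}
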