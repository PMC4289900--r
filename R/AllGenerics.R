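#' @include AllClasses.R
NULL

#' Total dendritic length of a morphology
#'
#' Sum of inter-node Euclidean distances over all dendritic edges (an edge is
#' dendritic when its child node is of type 3 or 4; soma-soma and axonal
#' edges are excluded), reported in millimetres.
#'
#' @param x a [NeuronMorphology-class] (or object containing one).
#' @return total dendritic length in mm.
#' @export
setGeneric("totalDendriticLength", function(x) standardGeneric("totalDendriticLength"))

#' Number of nodes / segments
#' @param x a morphology or compartment grid.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Node table accessor
#' @param x a [NeuronMorphology-class].
#' @return the node data.frame (SWC columns plus derived distances).
#' @export
setGeneric("morphNodes", function(x) standardGeneric("morphNodes"))

#' Section table accessor
#' @param x a [NeuronMorphology-class].
#' @return data.frame of unbranched sections.
#' @export
setGeneric("sectionTable", function(x) standardGeneric("sectionTable"))

#' Segment table accessor
#' @param x a [CompartmentGrid-class] or [CableModel-class].
#' @return data.frame of segments.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' Soma centroid (radius-weighted mean of type-1 nodes)
#' @param x a [NeuronMorphology-class].
#' @return numeric xyz in micrometres.
#' @export
setGeneric("somaCentroid", function(x) standardGeneric("somaCentroid"))

#' Frequencies of an impedance profile
#' @param x an [ImpedanceProfile-class].
#' @return numeric Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Complex impedance values of a profile
#' @param x an [ImpedanceProfile-class].
#' @return complex megaohms.
#' @export
setGeneric("impedanceValues", function(x) standardGeneric("impedanceValues"))

#' Members of a prune series
#' @param x a [PruneSeries-class].
#' @return list of [NeuronMorphology-class] objects, base first.
#' @export
setGeneric("seriesMembers", function(x) standardGeneric("seriesMembers"))

#' Achieved total dendritic lengths of a prune series
#' @param x a [PruneSeries-class].
#' @return numeric mm, base first.
#' @export
setGeneric("seriesLengths", function(x) standardGeneric("seriesLengths"))

#' Influence-field table accessor
#' @param x an [InfluenceField-class].
#' @return data.frame with x_um, m_org, m_new, IF, Lambda.
#' @export
setGeneric("fieldTable", function(x) standardGeneric("fieldTable"))
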