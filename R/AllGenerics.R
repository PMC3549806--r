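#' Accessors for pairPSSM classes
#'
#' `nContacts()` returns the number of contact residue pairs R;
#' `contactPairs()` the contact-pair table; `contactCutoff()` the distance
#' cutoff; `selfEnergy()` the template self-energy of a PairPSSM;
#' `nPositions()` its number of contact positions; `scoreTable()` the 20 x 20
#' score table at one contact position; `potentialMatrix()` and
#' `backgroundComposition()` the slots of an EmpiricalPotential;
#' `aaGroup()` the group index of amino acids under a GroupScheme.
#'
#' @param x an object of the relevant class.
#' @param r integer contact-position index.
#' @param aa character vector of one-letter amino-acid codes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname accessors
#' @export
setGeneric("contactCutoff", function(x) standardGeneric("contactCutoff"))

#' @rdname accessors
#' @export
setGeneric("selfEnergy", function(x) standardGeneric("selfEnergy"))

#' @rdname accessors
#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x, r) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("potentialMatrix", function(x) standardGeneric("potentialMatrix"))

#' @rdname accessors
#' @export
setGeneric("backgroundComposition",
           function(x) standardGeneric("backgroundComposition"))

#' @rdname accessors
#' @export
setGeneric("aaGroup", function(x, aa) standardGeneric("aaGroup"))

#' @rdname accessors
#' @export
setMethod("nContacts", "ContactMap", function(x) nrow(x@pairs))

#' @rdname accessors
#' @export
setMethod("nContacts", "TemplateDimer", function(x) nrow(x@contactMap@pairs))

#' @rdname accessors
#' @export
setMethod("contactPairs", "ContactMap", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("contactPairs", "TemplateDimer", function(x) x@contactMap@pairs)

#' @rdname accessors
#' @export
setMethod("contactCutoff", "ContactMap", function(x) x@cutoff)

#' @rdname accessors
#' @export
setMethod("selfEnergy", "PairPSSM", function(x) x@selfEnergy)

#' @rdname accessors
#' @export
setMethod("nPositions", "PairPSSM", function(x) length(x@scores))

#' @rdname accessors
#' @export
setMethod("scoreTable", "PairPSSM", function(x, r) x@scores[[r]])

#' @rdname accessors
#' @export
setMethod("potentialMatrix", "EmpiricalPotential", function(x) x@S)

#' @rdname accessors
#' @export
setMethod("backgroundComposition", "EmpiricalPotential", function(x) x@P)

#' @rdname accessors
#' @export
setMethod("aaGroup", "GroupScheme", function(x, aa) x@aaToGroup[aa])
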