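Example inputs in the dispermd topology / GRO text formats.

  opz_like_api.top / .gro   one donor-rich neutral API archetype (synthetic
                            toy molecule, not a real drug parameterization)
  has_like_chain10.top      a 10-monomer acetate-like excipient chain
                            (synthetic)

Load with read_topology() / read_structure(); the same files exercise the
`dispermd energy|rdf|hbonds|msd` command-line subcommands.
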