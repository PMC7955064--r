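# Synthetic VH framework template for the F02 heavy-chain library.
# This is a stand-in scaffold (human VH3-style frameworks) constructed for
# simulation and read extraction; it is NOT the clone's real framework,
# which is unpublished. 'X' marks the 17 diversified positions, in the
# order of the design file (28,31,33,50,51,52,54,55,56,58,96,97,99,100,
# 100a,100b,100c). All other residues are constant in every library member.
EVQLLESGGGLVQPGGSLRLSCAASGFXFSXYXMSWVRQAPGKGLEWVSXXXIXXXTXYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCDXXVXXXXXGAFDYWGQGTLVTVSS
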