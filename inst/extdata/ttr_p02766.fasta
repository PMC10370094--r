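>TTR_HUMAN transthyretin precursor (UniProt P02766)
MASHRLLLLCLAGLVFVSEAGPTGTGESKCPLMVKVLDAVRGSPAINVAVHVFRKAADDT
WEPFASGKTSESGELHGLTTEEEFVEGIYKVEIDTKSYWKALGISPFHEHAEVVFTANDS
GPRRYTIAALLSPYSYSTTAVVTNPKE
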