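strain	protein_id	family_id	tags
strain01	aroB_strain01	aroB	shikimate;aromatic
strain02	aroB_strain02	aroB	shikimate;aromatic
strain03	aroB_strain03	aroB	shikimate;aromatic
strain04	aroB_strain04	aroB	shikimate;aromatic
strain05	aroB_strain05	aroB	shikimate;aromatic
strain06	aroB_strain06	aroB	shikimate;aromatic
strain07	aroB_strain07	aroB	shikimate;aromatic
strain08	aroB_strain08	aroB	shikimate;aromatic
strain01	aroE_strain01	aroE	shikimate;aromatic
strain02	aroE_strain02	aroE	shikimate;aromatic
strain03	aroE_strain03	aroE	shikimate;aromatic
strain04	aroE_strain04	aroE	shikimate;aromatic
strain05	aroE_strain05	aroE	shikimate;aromatic
strain06	aroE_strain06	aroE	shikimate;aromatic
strain07	aroE_strain07	aroE	shikimate;aromatic
strain08	aroE_strain08	aroE	shikimate;aromatic
strain01	aroK_strain01	aroK	shikimate;aromatic
strain02	aroK_strain02	aroK	shikimate;aromatic
strain03	aroK_strain03	aroK	shikimate;aromatic
strain04	aroK_strain04	aroK	shikimate;aromatic
strain05	aroK_strain05	aroK	shikimate;aromatic
strain06	aroK_strain06	aroK	shikimate;aromatic
strain07	aroK_strain07	aroK	shikimate;aromatic
strain08	aroK_strain08	aroK	shikimate;aromatic
strain01	aroA_strain01	aroA	shikimate;aromatic
strain02	aroA_strain02	aroA	shikimate;aromatic
strain03	aroA_strain03	aroA	shikimate;aromatic
strain04	aroA_strain04	aroA	shikimate;aromatic
strain05	aroA_strain05	aroA	shikimate;aromatic
strain06	aroA_strain06	aroA	shikimate;aromatic
strain07	aroA_strain07	aroA	shikimate;aromatic
strain08	aroA_strain08	aroA	shikimate;aromatic
strain01	aroC_strain01	aroC	shikimate;aromatic
strain02	aroC_strain02	aroC	shikimate;aromatic
strain03	aroC_strain03	aroC	shikimate;aromatic
strain04	aroC_strain04	aroC	shikimate;aromatic
strain05	aroC_strain05	aroC	shikimate;aromatic
strain06	aroC_strain06	aroC	shikimate;aromatic
strain07	aroC_strain07	aroC	shikimate;aromatic
strain08	aroC_strain08	aroC	shikimate;aromatic
strain01	patchA_strain01	patchA	glycolysis
strain02	patchA_strain02	patchA	glycolysis
strain04	patchA_strain04	patchA	glycolysis
strain05	patchA_strain05	patchA	glycolysis
strain06	patchA_strain06	patchA	glycolysis
strain07	patchA_strain07	patchA	glycolysis
strain08	patchA_strain08	patchA	glycolysis
strain01	dupB_strain01	dupB	shikimate
strain02	dupB_strain02	dupB	shikimate
strain03	dupB_strain03	dupB	shikimate
strain04	dupB_strain04	dupB	shikimate
strain05	dupB_strain05	dupB	shikimate
strain06	dupB_strain06	dupB	shikimate
strain07	dupB_strain07	dupB	shikimate
strain08	dupB_strain08	dupB	shikimate
strain05	dupB_strain05_copy2	dupB	shikimate
strain01	patchC_strain01	patchC	
strain03	patchC_strain03	patchC	
strain04	patchC_strain04	patchC	
strain05	patchC_strain05	patchC	
strain06	patchC_strain06	patchC	
strain08	patchC_strain08	patchC	
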