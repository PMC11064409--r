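code,description
Z93.1,Gastrostomy status (synthetic placeholder entry)
R63.3,Feeding difficulties (synthetic placeholder entry)
P92,Feeding problems of newborn (synthetic placeholder entry)
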