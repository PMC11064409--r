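code,description
Z99.1,Dependence on respirator/ventilator (synthetic placeholder entry)
Z93.0,Tracheostomy status (synthetic placeholder entry)
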