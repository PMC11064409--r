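code,description
F80,Specific developmental disorders of speech and language (synthetic placeholder entry)
F82,Specific developmental disorder of motor function (synthetic placeholder entry)
F88,Other disorders of psychological development (synthetic placeholder entry)
F89,Unspecified disorder of psychological development (synthetic placeholder entry)
R62.0,Delayed milestone in childhood (synthetic placeholder entry)
R62.5,Unspecified lack of expected physiological development (synthetic placeholder entry)
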