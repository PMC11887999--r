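trigger,effect_field,effect_value,direction,scope
no,negated,true,forward,5
not,negated,true,forward,5
denies,negated,true,forward,5
without,negated,true,forward,5
geen,negated,true,forward,5
niet,negated,true,forward,5
ontkent,negated,true,forward,5
zonder,negated,true,forward,5
history of,temporality,historical,forward,5
previous,temporality,historical,forward,5
voorgeschiedenis van,temporality,historical,forward,5
eerder,temporality,historical,forward,5
if,temporality,hypothetical,forward,5
risk of,temporality,hypothetical,forward,5
indien,temporality,hypothetical,forward,5
risico op,temporality,hypothetical,forward,5
family,experiencer,other,forward,5
mother,experiencer,other,forward,5
father,experiencer,other,forward,5
familie,experiencer,other,forward,5
moeder,experiencer,other,forward,5
vader,experiencer,other,forward,5
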