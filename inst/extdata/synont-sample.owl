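<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="Deficient cold syndrome">
    <owl:equivalentClass rdf:resource="Cold syndrome"/>
    <owl:equivalentClass rdf:resource="Yang deficient syndrome"/>
  </owl:Class>
  <owl:Class rdf:about="Qi stagnation and blood stasis">
    <owl:equivalentClass>
      <owl:Restriction>
        <owl:onProperty rdf:resource="subsume"/>
        <owl:someValuesFrom rdf:resource="Qi stagnation syndrome"/>
      </owl:Restriction>
    </owl:equivalentClass>
    <owl:equivalentClass>
      <owl:Restriction>
        <owl:onProperty rdf:resource="subsume"/>
        <owl:someValuesFrom rdf:resource="Blood stasis syndrome"/>
      </owl:Restriction>
    </owl:equivalentClass>
    <rdfs:subClassOf rdf:resource="Excess syndrome"/>
  </owl:Class>
</rdf:RDF>
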