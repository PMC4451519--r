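<?xml version="1.0" encoding="UTF-8"?>
<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
  <map language="process description" id="fig4_like">
    <glyph class="compartment" id="cp_cyto">
      <label text="cytosol"/>
      <bbox x="0" y="0" w="900" h="400"/>
    </glyph>
    <glyph class="macromolecule" id="ep_k1" compartmentRef="cp_cyto">
      <label text="kinase1"/>
      <bbox x="100" y="100" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_k2" compartmentRef="cp_cyto">
      <label text="kinase2"/>
      <bbox x="100" y="100" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_rsk0" compartmentRef="cp_cyto">
      <label text="RSK"/>
      <bbox x="100" y="100" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_rsk1" compartmentRef="cp_cyto">
      <label text="RSK-P"/>
      <bbox x="100" y="100" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_rsk2" compartmentRef="cp_cyto">
      <label text="RSK-PP"/>
      <bbox x="100" y="100" w="80" h="40"/>
    </glyph>
    <glyph class="process" id="pr_p1" compartmentRef="cp_cyto">
      <bbox x="250" y="120" w="20" h="20"/>
    </glyph>
    <glyph class="process" id="pr_p2" compartmentRef="cp_cyto">
      <bbox x="550" y="120" w="20" h="20"/>
    </glyph>
    <arc class="consumption" id="arc1" source="ep_rsk0" target="pr_p1"/>
    <arc class="production" id="arc2" source="pr_p1" target="ep_rsk1"/>
    <arc class="catalysis" id="arc3" source="ep_k1" target="pr_p1"/>
    <arc class="consumption" id="arc4" source="ep_rsk1" target="pr_p2"/>
    <arc class="production" id="arc5" source="pr_p2" target="ep_rsk2"/>
    <arc class="catalysis" id="arc6" source="ep_k2" target="pr_p2"/>
  </map>
</sbgn>
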