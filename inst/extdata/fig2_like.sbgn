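<?xml version="1.0" encoding="UTF-8"?>
<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
  <map language="process description" id="fig2_like">
    <glyph class="compartment" id="cp_cyto">
      <label text="muscle cytosol"/>
      <bbox x="0" y="0" w="1000" h="700"/>
    </glyph>
    <glyph class="complex" id="cx_actmyo" compartmentRef="cp_cyto">
      <label text="actin-myosin"/>
      <bbox x="40" y="60" w="220" h="160"/>
      <glyph class="complex" id="cx_myosin">
        <label text="myosin complex"/>
        <bbox x="60" y="80" w="120" h="90"/>
        <glyph class="macromolecule" id="m_mlc">
          <label text="myosin light chain"/>
          <bbox x="70" y="130" w="80" h="40"/>
        </glyph>
        <glyph class="macromolecule" id="m_myosin">
          <label text="myosin"/>
          <bbox x="70" y="90" w="80" h="40"/>
        </glyph>
      </glyph>
      <glyph class="macromolecule" id="m_actin">
        <label text="actin"/>
        <bbox x="60" y="180" w="80" h="40"/>
      </glyph>
    </glyph>
    <glyph class="simple chemical" id="ep_adp" compartmentRef="cp_cyto">
      <label text="ADP"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_amact" compartmentRef="cp_cyto">
      <label text="active actomyosin"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_atp" compartmentRef="cp_cyto">
      <label text="ATP"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_ca" compartmentRef="cp_cyto">
      <label text="Ca2+"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_mlck" compartmentRef="cp_cyto">
      <label text="MLCK"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_myop" compartmentRef="cp_cyto">
      <label text="myosin-P"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_x1" compartmentRef="cp_cyto">
      <label text="bystanderA"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="simple chemical" id="ep_x2" compartmentRef="cp_cyto">
      <label text="bystanderA-P"/>
      <bbox x="400" y="100" w="40" h="40"/>
    </glyph>
    <glyph class="process" id="pr_bind" compartmentRef="cp_cyto">
      <bbox x="600" y="100" w="20" h="20"/>
    </glyph>
    <glyph class="process" id="pr_contract" compartmentRef="cp_cyto">
      <bbox x="600" y="100" w="20" h="20"/>
    </glyph>
    <glyph class="process" id="pr_other" compartmentRef="cp_cyto">
      <bbox x="600" y="100" w="20" h="20"/>
    </glyph>
    <arc class="consumption" id="arc1" source="cx_myosin" target="pr_bind"/>
    <arc class="production" id="arc10" source="pr_other" target="ep_x2"/>
    <arc class="catalysis" id="arc11" source="ep_myop" target="pr_other"/>
    <arc class="consumption" id="arc2" source="ep_atp" target="pr_bind"/>
    <arc class="production" id="arc3" source="pr_bind" target="ep_myop"/>
    <arc class="production" id="arc4" source="pr_bind" target="ep_adp"/>
    <arc class="catalysis" id="arc5" source="ep_mlck" target="pr_bind"/>
    <arc class="consumption" id="arc6" source="cx_actmyo" target="pr_contract"/>
    <arc class="consumption" id="arc7" source="ep_ca" target="pr_contract"/>
    <arc class="production" id="arc8" source="pr_contract" target="ep_amact"/>
    <arc class="consumption" id="arc9" source="ep_x1" target="pr_other"/>
  </map>
</sbgn>
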